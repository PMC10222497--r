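#' Tokenize a SMILES string into SMILES atoms
#'
#' Splits a SMILES line into its indivisible units ("SMILES atoms"): most
#' single characters stand alone, while a small set of multi-character
#' constructs are kept whole.  The descriptor machinery treats SMILES purely
#' as symbol sequences, so no chemistry (valence, aromaticity) is perceived.
#'
#' The token table is:
#' \itemize{
#'   \item bracket atom blocks \code{"[...]"} (kept whole, e.g. \code{"[N+]"}),
#'   \item the two-letter organic-subset elements \code{"Cl"} and \code{"Br"},
#'   \item ring-bond escapes \code{"\%"} followed by two digits (e.g. \code{"\%11"}),
#'   \item the chirality mark \code{"@@"},
#'   \item every other printable ASCII character as a single token.
#' }
#'
#' @param smiles A single SMILES string (printable ASCII).
#' @return Character vector of tokens, in order.  The empty string yields
#'   \code{character(0)} (a degenerate compound, not an error).
#'   Pasting the tokens back together always reproduces the input.
#' @examples
#' smiles_tokenize("C=O")
#' smiles_tokenize("ClCCl")
#' smiles_tokenize("C%11")
#' @export
smiles_tokenize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stop("'smiles' must be a single non-NA character string")
  n <- nchar(smiles)
  if (n == 0L) return(character(0))
  codes <- utf8ToInt(smiles)
  bad <- which(codes < 32L | codes > 126L)
  if (length(bad))
    stop(sprintf("unrecognized character at position %d in %s",
                 bad[1], deparse(smiles)))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  out <- character(n)   # at most n tokens
  k <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n)
        stop(sprintf("unclosed bracket atom starting at position %d", i))
      tok <- substr(smiles, i, j)
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !all(chars[i + 1:2] %in% as.character(0:9)))
        stop(sprintf("ring-bond escape '%%' at position %d must be followed by two digits", i))
      tok <- substr(smiles, i, i + 2L)
      i <- i + 3L
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      tok <- "Cl"; i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      tok <- "Br"; i <- i + 2L
    } else if (ch == "@" && i < n && chars[i + 1L] == "@") {
      tok <- "@@"; i <- i + 2L
    } else {
      tok <- ch; i <- i + 1L
    }
    k <- k + 1L
    out[k] <- tok
  }
  out[seq_len(k)]
}

# Element-wise minimum of two character vectors in C-locale byte order.
# Locale-independent (radix order), so canonical attribute keys are stable
# across platforms.
str_pmin <- function(x, y) {
  u <- sort(unique(c(x, y)), method = "radix")
  ifelse(match(x, u) <= match(y, u), x, y)
}

#' Extract single/pair/triple attributes from a token sequence
#'
#' Every token yields an S attribute, every adjacent pair an SS attribute and
#' every adjacent triple an SSS attribute.  Pair and triple keys are
#' direction-independent: the forward and reversed reading of a window map to
#' the same canonical key (the lexicographically smaller of the two joins in
#' byte order), so a compound read backwards produces the same SS/SSS
#' multiset.
#'
#' Keys are encoded as \code{"<kind>|<tok1>|..."}, e.g. \code{"S|C"},
#' \code{"SS|=|C"}.
#'
#' @param atoms Character vector of tokens from [smiles_tokenize()].
#' @return Named integer vector of class \code{"attribute_profile"}: names are
#'   canonical attribute keys, values are multiplicities.  For \code{m} tokens
#'   the S/SS/SSS multiplicities total \code{m}, \code{max(m-1,0)} and
#'   \code{max(m-2,0)}.
#' @examples
#' attribute_profile(smiles_tokenize("C=O"))
#' @export
attribute_profile <- function(atoms) {
  stopifnot(is.character(atoms))
  m <- length(atoms)
  keys <- paste0("S|", atoms)
  if (m >= 2L) {
    fwd <- paste(atoms[-m], atoms[-1L], sep = "|")
    rev <- paste(atoms[-1L], atoms[-m], sep = "|")
    keys <- c(keys, paste0("SS|", str_pmin(fwd, rev)))
  }
  if (m >= 3L) {
    a <- atoms[seq_len(m - 2L)]
    b <- atoms[1L + seq_len(m - 2L)]
    c3 <- atoms[2L + seq_len(m - 2L)]
    fwd <- paste(a, b, c3, sep = "|")
    rev <- paste(c3, b, a, sep = "|")
    keys <- c(keys, paste0("SSS|", str_pmin(fwd, rev)))
  }
  tab <- table(keys)
  structure(as.integer(tab), names = names(tab), class = "attribute_profile")
}

#' Attribute profiles for a vector of SMILES
#'
#' @param smiles Character vector of SMILES strings.
#' @return List of [attribute_profile()] objects, one per compound.
#' @export
smiles_profiles <- function(smiles) {
  lapply(smiles, function(s) attribute_profile(smiles_tokenize(s)))
}

attr_kind <- function(key) sub("\\|.*$", "", key)
attr_token <- function(key) sub("^[^|]*\\|", "", key)

#' Build the attribute vocabulary from active-training profiles
#'
#' Counts, for each attribute, the number of distinct active-training
#' compounds that carry it (document frequency) and flags attributes seen in
#' fewer than \code{T} compounds as rare.  Rare attributes keep a correlation
#' weight of exactly 0 and never contribute to the descriptor; attributes
#' absent from this vocabulary are treated the same way at prediction time.
#'
#' @param profiles List of [attribute_profile()] objects from the ACTIVE
#'   training set only (the set that builds the model).
#' @param T Rarity threshold, a positive integer (typically 1, 2 or 3).  An
#'   attribute is non-rare iff its document frequency is at least \code{T}.
#' @return A \code{cw_table}: data frame with columns \code{key}, \code{kind}
#'   (S/SS/SSS), \code{token}, \code{frequency}, \code{rare}, \code{cw}
#'   (initialised to 0).
#' @export
build_vocabulary <- function(profiles, T = 1L) {
  if (!is.list(profiles) || length(profiles) == 0L)
    stop("'profiles' must be a non-empty list of attribute profiles")
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("'T' must be a positive integer")
  df <- table(unlist(lapply(profiles, names), use.names = FALSE))
  key <- sort(names(df), method = "radix")
  frequency <- as.integer(df[key])
  out <- data.frame(
    key = key,
    kind = attr_kind(key),
    token = attr_token(key),
    frequency = frequency,
    rare = frequency < T,
    cw = 0,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cw_table", "data.frame")
  attr(out, "T") <- T
  out
}

#' @export
print.cw_table <- function(x, ...) {
  cat(sprintf("Correlation-weight table: %d attributes (%d non-rare, T = %s)\n",
              nrow(x), sum(!x$rare), attr(x, "T")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Write the token/attribute table as plain text
#'
#' One attribute per line: kind, token, document frequency, rare flag,
#' correlation weight (tab-separated, with header).
#'
#' @param table A \code{cw_table}.
#' @param path Output file path.
#' @export
write_vocabulary <- function(table, path) {
  stopifnot(inherits(table, "cw_table"))
  utils::write.table(
    as.data.frame(table)[c("kind", "token", "frequency", "rare", "cw")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Sparse compound-by-attribute count matrix over a fixed key set.
# Rows follow 'profiles'; columns follow 'keys'; entries are multiplicities.
attribute_matrix <- function(profiles, keys) {
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    j <- match(names(p), keys)
    keep <- !is.na(j)
    if (any(keep)) {
      ii <- c(ii, rep.int(i, sum(keep)))
      jj <- c(jj, j[keep])
      xx <- c(xx, as.integer(p[keep]))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(xx),
                       dims = c(length(profiles), length(keys)))
}
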