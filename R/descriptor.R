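#' Optimal descriptor DCW(T, N)
#'
#' Sum of correlation weights over all attribute occurrences of a compound:
#' an attribute occurring k times contributes k times its weight.  Rare
#' attributes and attributes absent from the table contribute exactly 0.
#'
#' @param profile An [attribute_profile()].
#' @param table A \code{cw_table} with fitted (or zero) weights.
#' @return A single numeric descriptor value; 0 for an empty profile.
#' @export
compute_dcw <- function(profile, table) {
  stopifnot(inherits(table, "cw_table"))
  if (length(profile) == 0L) return(0)
  j <- match(names(profile), table$key)
  keep <- !is.na(j)
  if (!any(keep)) return(0)
  j <- j[keep]
  w <- ifelse(table$rare[j], 0, table$cw[j])
  sum(as.numeric(profile[keep]) * w)
}

#' Calibrate the semi-correlation line
#'
#' Ordinary least squares of the binary endpoint on the descriptor,
#' y = C0 + C1 * DCW, fitted on the active training set.  With a {0,1}
#' response this is the "semi-correlation": a regression line whose fitted
#' value is later thresholded at 0.5 to classify.
#'
#' @param dcw_values Numeric descriptor values.
#' @param labels Binary endpoint values (0/1), same length.
#' @return Named numeric vector \code{c(C0 = intercept, C1 = slope)}.
#' @export
fit_line <- function(dcw_values, labels) {
  x <- as.numeric(dcw_values)
  y <- as.numeric(labels)
  if (length(x) != length(y)) stop("length mismatch between dcw and labels")
  if (length(x) < 2L) stop("need at least 2 points to fit the line")
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0)
    stop("degenerate descriptor: zero variance in DCW")
  c1 <- stats::cov(x, y) / vx
  c0 <- mean(y) - c1 * mean(x)
  c(C0 = c0, C1 = c1)
}

#' Construct a semi-correlation model object
#'
#' The deployable classifier: a frozen correlation-weight table, the rarity
#' threshold T, the number of optimization epochs behind the returned
#' weights, the regression coefficients and the 0.5 decision threshold.
#'
#' @param cw_table A \code{cw_table} with weights.
#' @param T Rarity threshold used to build the vocabulary.
#' @param N Epoch count the weights correspond to.
#' @param C0,C1 Intercept and slope of the semi-correlation line.
#' @param threshold Decision threshold on the fitted value (default 0.5;
#'   the boundary itself classifies as active).
#' @return Object of class \code{"semicor_model"}.
#' @export
semicor_model <- function(cw_table, T, N, C0, C1, threshold = 0.5) {
  stopifnot(inherits(cw_table, "cw_table"), is.finite(C0), is.finite(C1))
  structure(
    list(cw_table = cw_table, T = as.integer(T), N = as.integer(N),
         C0 = as.numeric(C0), C1 = as.numeric(C1),
         threshold = as.numeric(threshold)),
    class = "semicor_model")
}

#' @export
print.semicor_model <- function(x, ...) {
  cat("Semi-correlation SMILES classifier\n")
  cat(sprintf("  attributes: %d (%d non-rare), T = %d, epochs N = %d\n",
              nrow(x$cw_table), sum(!x$cw_table$rare), x$T, x$N))
  cat(sprintf("  y = %.6g + %.6g * DCW;  active iff y >= %g\n",
              x$C0, x$C1, x$threshold))
  invisible(x)
}

#' Predict activity categories from a semi-correlation model
#'
#' Computes y = C0 + C1 * DCW for each compound and classifies it active
#' (1) when y is at or above the threshold, inactive (0) below it.
#' Attributes unknown to the model (never seen in active training, or rare)
#' contribute 0 to the descriptor and are tallied per compound.
#'
#' @param object A \code{"semicor_model"}.
#' @param newdata Character vector of SMILES, or a list of
#'   [attribute_profile()] objects.
#' @param ... Unused.
#' @return Data frame with columns \code{dcw}, \code{y}, \code{category}
#'   and \code{unknown_attributes} (occurrences, with multiplicity, that
#'   carried no weight).  A \code{smiles} column is prepended when
#'   \code{newdata} is character.
#' @export
predict.semicor_model <- function(object, newdata, ...) {
  if (is.character(newdata)) {
    profiles <- smiles_profiles(newdata)
    smiles <- newdata
  } else if (is.list(newdata)) {
    profiles <- newdata
    smiles <- NULL
  } else stop("'newdata' must be SMILES strings or a list of profiles")
  tab <- object$cw_table
  dcw <- vapply(profiles, compute_dcw, numeric(1), table = tab)
  live <- tab$key[!tab$rare]
  unknown <- vapply(profiles, function(p) {
    if (length(p) == 0L) return(0L)
    sum(as.integer(p[!(names(p) %in% live)]))
  }, integer(1))
  y <- object$C0 + object$C1 * dcw
  out <- data.frame(dcw = dcw, y = y,
                    category = as.integer(y >= object$threshold),
                    unknown_attributes = unknown)
  if (!is.null(smiles)) out <- cbind(smiles = smiles, out)
  out
}

#' Serialize a model to a plain-text file
#'
#' Writes a header (T, N, C0, C1, threshold, with coefficients and weights
#' at full double precision) followed by one line per attribute.  Reloading
#' with [read_model()] reproduces predictions bit-exactly.
#'
#' @param model A \code{"semicor_model"}.
#' @param path Output file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "semicor_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# semicor model v1",
    sprintf("T\t%d", model$T),
    sprintf("N\t%d", model$N),
    sprintf("C0\t%.17g", model$C0),
    sprintf("C1\t%.17g", model$C1),
    sprintf("threshold\t%.17g", model$threshold),
    "kind\ttoken\tcw\tfrequency\trare"), con)
  tab <- model$cw_table
  writeLines(sprintf("%s\t%s\t%.17g\t%d\t%d",
                     tab$kind, tab$token, tab$cw, tab$frequency,
                     as.integer(tab$rare)), con)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path Path to a model file.
#' @return A \code{"semicor_model"}.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L || lines[1] != "# semicor model v1")
    stop("not a semicor model file: ", path)
  hdr <- strsplit(lines[2:6], "\t", fixed = TRUE)
  hv <- stats::setNames(vapply(hdr, `[`, "", 2L), vapply(hdr, `[`, "", 1L))
  body <- lines[-(1:7)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    kind <- vapply(parts, `[`, "", 1L)
    token <- vapply(parts, `[`, "", 2L)
    tab <- data.frame(
      key = paste(kind, token, sep = "|"),
      kind = kind,
      token = token,
      frequency = as.integer(vapply(parts, `[`, "", 4L)),
      rare = as.integer(vapply(parts, `[`, "", 5L)) == 1L,
      cw = as.numeric(vapply(parts, `[`, "", 3L)),
      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(key = character(0), kind = character(0),
                      token = character(0), frequency = integer(0),
                      rare = logical(0), cw = numeric(0))
  }
  class(tab) <- c("cw_table", "data.frame")
  attr(tab, "T") <- as.integer(hv[["T"]])
  semicor_model(tab, T = as.integer(hv[["T"]]), N = as.integer(hv[["N"]]),
                C0 = as.numeric(hv[["C0"]]), C1 = as.numeric(hv[["C1"]]),
                threshold = as.numeric(hv[["threshold"]]))
}
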