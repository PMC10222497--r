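#' Random four-way splits of a compound table
#'
#' Partitions \code{n_compounds} indices into active training, passive
#' training, calibration and validation subsets of about 25% each (sizes as
#' even as n allows; remainders go to the calibration and validation ends).
#' Each of the k splits uses an independent sub-seed, so the whole system is
#' reproducible from one integer.
#'
#' @param n_compounds Number of compounds (>= 8).
#' @param k Number of independent splits (>= 1).
#' @param seed Top-level integer seed.
#' @return List of k \code{"four_way_split"} objects, each with integer
#'   index fields \code{active_training}, \code{passive_training},
#'   \code{calibration}, \code{validation}.
#' @export
make_splits <- function(n_compounds, k = 1L, seed = 1L) {
  n <- as.integer(n_compounds); k <- as.integer(k)
  if (is.na(n) || n < 8L) stop("need at least 8 compounds to split four ways")
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
  base <- n %/% 4L
  sizes <- rep(base, 4L)
  rem <- n %% 4L
  if (rem > 0L) sizes[4L - seq_len(rem) + 1L] <- base + 1L
  lapply(seq_len(k), function(i) {
    set.seed(derive_seed(seed, paste0("split", i)))
    perm <- sample.int(n)
    ends <- cumsum(sizes)
    structure(list(
      active_training  = sort(perm[seq_len(sizes[1])]),
      passive_training = sort(perm[(ends[1] + 1L):ends[2]]),
      calibration      = sort(perm[(ends[2] + 1L):ends[3]]),
      validation       = sort(perm[(ends[3] + 1L):ends[4]])),
      class = "four_way_split")
  })
}

#' @export
print.four_way_split <- function(x, ...) {
  cat(sprintf("Four-way split: AT %d / PT %d / C %d / V %d compounds\n",
              length(x$active_training), length(x$passive_training),
              length(x$calibration), length(x$validation)))
  invisible(x)
}

split_sets <- c("active_training", "passive_training",
                "calibration", "validation")

#' Cross-split MCC matrix of a system of self-consistent models
#'
#' Entry (i, j) is the Matthews correlation coefficient of model i's
#' predictions on split j's validation compounds.  The diagonal is each
#' model's ordinary validation MCC.  Validation compounds that happen to
#' overlap model i's training material are not excluded — the protocol
#' evaluates sets as-is, and [validation_overlap()] makes the overlap
#' visible instead.
#'
#' @param models List of k \code{"semicor_model"} objects; model i must
#'   have been trained on split i.
#' @param splits List of k \code{"four_way_split"} objects.
#' @param data Compound table: data frame with \code{smiles} and
#'   \code{label} columns indexed by the splits.
#' @return k x k numeric matrix of class \code{"consistency_matrix"}.
#' @export
build_matrix <- function(models, splits, data) {
  k <- length(models)
  if (k != length(splits))
    stop("need as many models as splits (one model per split)")
  profiles <- smiles_profiles(data$smiles)
  mat <- matrix(NA_real_, k, k,
                dimnames = list(model = paste0("M", seq_len(k)),
                                validation = paste0("V", seq_len(k))))
  for (i in seq_len(k)) {
    pred_all <- predict(models[[i]], profiles)
    for (j in seq_len(k)) {
      idx <- splits[[j]]$validation
      mat[i, j] <- mcc_score(data$label[idx], pred_all$category[idx])
    }
  }
  structure(mat, class = c("consistency_matrix", class(mat)))
}

#' Summarise a consistency matrix
#'
#' Mean and population standard deviation of the k(k-1) off-diagonal cells
#' (the self-consistency measure: how well each model predicts the other
#' splits' validation sets), plus the mean over all k^2 cells.
#'
#' @param matrix A k x k consistency matrix, k >= 2.
#' @return List with \code{mean_offdiag}, \code{sd_offdiag},
#'   \code{mean_all}.
#' @export
summarize_consistency <- function(matrix) {
  k <- nrow(matrix)
  if (is.null(k) || k < 2L || ncol(matrix) != k)
    stop("need a square matrix with k >= 2")
  off <- matrix[row(matrix) != col(matrix)]
  m <- mean(off)
  list(mean_offdiag = m,
       sd_offdiag = sqrt(mean((off - m)^2)),
       mean_all = mean(matrix))
}

#' Jaccard overlap between validation sets
#'
#' Symmetric k x k matrix of Jaccard indices |Vi and Vj| / |Vi or Vj|
#' between the validation subsets of the splits; diagonal 1.  Reported
#' alongside the consistency matrix so the contamination of cross-split
#' evaluation is visible.
#'
#' @param splits List of \code{"four_way_split"} objects, k >= 2.
#' @return k x k numeric matrix.
#' @export
validation_overlap <- function(splits) {
  k <- length(splits)
  if (k < 2L) stop("need at least 2 splits")
  out <- diag(1, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- splits[[i]]$validation; b <- splits[[j]]$validation
    jac <- length(intersect(a, b)) / length(union(a, b))
    out[i, j] <- out[j, i] <- jac
  }
  dimnames(out) <- list(paste0("V", seq_len(k)), paste0("V", seq_len(k)))
  out
}
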