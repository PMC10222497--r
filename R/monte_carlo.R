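#' Configuration for the Monte Carlo correlation-weight optimization
#'
#' @param target Target function: \code{"TF1"} (training correlation balance
#'   plus calibration-set IIC, the default) or \code{"TF0"} (training only).
#' @param T Rarity threshold for the vocabulary (attributes in fewer than T
#'   active-training compounds are excluded; typically 1, 2 or 3).
#' @param n_epochs Number of optimization epochs; one epoch visits every
#'   non-rare attribute once in seeded-random order.
#' @param step Half-width of the uniform weight perturbation: a visit
#'   proposes cw' = cw + u with u ~ U(-step, step).
#' @param init_low,init_high Range of the uniform random weight
#'   initialization (nonzero so the initial descriptor is non-degenerate).
#' @param seed Top-level integer seed; init and move streams are derived
#'   from it.
#' @param tf0_penalty Gap penalty factor in TF0 (default 0.1).
#' @param iic_weight Weight of the calibration IIC in TF1 (default 0.5).
#' @return Object of class \code{"optimizer_config"}.
#' @export
optimizer_config <- function(target = c("TF1", "TF0"), T = 1L,
                             n_epochs = 40L, step = 0.1,
                             init_low = 0.5, init_high = 1.5,
                             seed = 1L, tf0_penalty = 0.1,
                             iic_weight = 0.5) {
  target <- match.arg(target)
  stopifnot(T >= 1L, n_epochs >= 0L, step > 0, init_low <= init_high)
  structure(list(target = target, T = as.integer(T),
                 n_epochs = as.integer(n_epochs), step = step,
                 init_low = init_low, init_high = init_high,
                 seed = as.integer(seed), tf0_penalty = tf0_penalty,
                 iic_weight = iic_weight),
            class = "optimizer_config")
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# rows/values of every column of a dgCMatrix, precomputed for fast
# single-attribute descriptor updates
sparse_columns <- function(M) {
  p <- M@p; i <- M@i; x <- M@x
  lapply(seq_len(ncol(M)), function(j) {
    if (p[j + 1L] > p[j]) {
      sel <- (p[j] + 1L):p[j + 1L]
      list(r = i[sel] + 1L, v = x[sel])
    } else NULL
  })
}

#' Monte Carlo optimization of correlation weights
#'
#' Greedy coordinate Monte Carlo search: per epoch every non-rare attribute
#' is visited once in seeded-random order; each visit proposes a uniform
#' perturbation of that attribute's weight, the semi-correlation line is
#' refitted on the active training set, and the move is kept iff the target
#' function does not decrease.  TF0 is computed from the active and passive
#' training correlations; TF1 additionally rewards the calibration-set IIC.
#' Validation-set metrics are recorded per epoch for reporting but never
#' influence the optimization.
#'
#' The returned model is the snapshot from the epoch with maximal
#' calibration-set MCC (earliest epoch on ties) — the overtraining guard:
#' optimization past the calibration peak improves training fit at the
#' expense of new compounds, so the peak epoch is the deployable model.
#'
#' @param data Compound table: data frame with \code{smiles} (character)
#'   and \code{label} (0/1) columns.
#' @param split A \code{"four_way_split"} over \code{data}'s rows; the
#'   vocabulary is built from its active training set only.
#' @param config An [optimizer_config()].
#' @return Object of class \code{"mc_fit"}: list with \code{model} (the
#'   best-calibration snapshot, a \code{"semicor_model"}), \code{final_model}
#'   (weights after the last epoch), \code{history} (one row per epoch:
#'   epoch, tf, r and MCC for all four sets), \code{chosen_epoch},
#'   \code{vocabulary_size} and the \code{config}.
#' @export
mc_optimize <- function(data, split, config = optimizer_config()) {
  stopifnot(inherits(split, "four_way_split"),
            inherits(config, "optimizer_config"),
            is.data.frame(data), all(c("smiles", "label") %in% names(data)))
  if (!all(data$label %in% 0:1)) stop("labels must be 0 or 1")
  idx <- list(at = split$active_training, pt = split$passive_training,
              c = split$calibration, v = split$validation)
  if (any(lengths(idx) == 0L)) stop("all four subsets must be non-empty")
  if (anyDuplicated(unlist(idx))) stop("split subsets must be disjoint")

  profiles <- smiles_profiles(data$smiles)
  vocab <- build_vocabulary(profiles[idx$at], config$T)
  keys <- vocab$key[!vocab$rare]
  V <- length(keys)
  if (V == 0L) stop("empty non-rare vocabulary: lower T or add compounds")

  X <- lapply(idx, function(ii) attribute_matrix(profiles[ii], keys))
  cols <- lapply(X, sparse_columns)
  lab <- lapply(idx, function(ii) as.numeric(data$label[ii]))

  set.seed(derive_seed(config$seed, "init"))
  cw <- stats::runif(V, config$init_low, config$init_high)
  dcw <- lapply(X, function(M) as.numeric(M %*% cw))
  use_iic <- config$target == "TF1"

  objective <- function(d_at, d_pt, d_c) {
    vx <- stats::var(d_at)
    if (!is.finite(vx) || vx == 0) return(list(tf = -Inf))
    c1 <- stats::cov(d_at, lab$at) / vx
    c0 <- mean(lab$at) - c1 * mean(d_at)
    if (c1 == 0) return(list(tf = -Inf))
    # cor(lab, c0 + c1*d) = sign(c1) * cor(lab, d)
    r_at <- safe_cor(lab$at, d_at) * sign(c1)
    r_pt <- safe_cor(lab$pt, d_pt) * sign(c1)
    if (is.na(r_at) || is.na(r_pt)) return(list(tf = -Inf))
    tf <- tf0(r_at, r_pt, config$tf0_penalty)
    if (use_iic) {
      ic <- tryCatch(iic(lab$c, c0 + c1 * d_c), error = function(e) NA_real_)
      if (is.na(ic)) return(list(tf = -Inf))
      tf <- tf1(tf, ic, config$iic_weight)
    }
    list(tf = tf, C0 = c0, C1 = c1)
  }

  cur <- objective(dcw$at, dcw$pt, dcw$c)
  if (!is.finite(cur$tf) && is.null(cur$C0)) {
    fit0 <- tryCatch(fit_line(dcw$at, lab$at), error = function(e)
      stop("degenerate initial descriptor on the active training set"))
    cur$C0 <- fit0[["C0"]]; cur$C1 <- fit0[["C1"]]
  }
  C0 <- cur$C0; C1 <- cur$C1; tf_cur <- cur$tf

  hist_rows <- vector("list", config$n_epochs)
  best <- NULL
  shift <- function(d, col, u) {
    if (!is.null(col)) d[col$r] <- d[col$r] + u * col$v
    d
  }

  set.seed(derive_seed(config$seed, "moves"))
  for (epoch in seq_len(config$n_epochs)) {
    ord <- sample.int(V)
    for (j in ord) {
      u <- stats::runif(1, -config$step, config$step)
      d_at <- shift(dcw$at, cols$at[[j]], u)
      d_pt <- shift(dcw$pt, cols$pt[[j]], u)
      d_c <- if (use_iic) shift(dcw$c, cols$c[[j]], u) else NULL
      o <- objective(d_at, d_pt, d_c)
      if (is.finite(o$tf) && o$tf >= tf_cur) {
        cw[j] <- cw[j] + u
        dcw$at <- d_at; dcw$pt <- d_pt
        if (use_iic) dcw$c <- d_c
        C0 <- o$C0; C1 <- o$C1; tf_cur <- o$tf
      }
    }
    if (!use_iic) dcw$c <- as.numeric(X$c %*% cw)
    dcw$v <- as.numeric(X$v %*% cw)
    y <- lapply(dcw, function(d) C0 + C1 * d)
    r <- vapply(names(y), function(s) safe_cor(lab[[s]], y[[s]]), numeric(1))
    mcc <- vapply(names(y), function(s)
      mcc_score(lab[[s]], as.integer(y[[s]] >= 0.5)), numeric(1))
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, tf = tf_cur,
      r_at = r[["at"]], r_pt = r[["pt"]], r_c = r[["c"]], r_v = r[["v"]],
      mcc_at = mcc[["at"]], mcc_pt = mcc[["pt"]],
      mcc_c = mcc[["c"]], mcc_v = mcc[["v"]])
    if (!is.na(mcc[["c"]]) &&
        (is.null(best) || mcc[["c"]] > best$mcc_c)) {
      best <- list(cw = cw, C0 = C0, C1 = C1, epoch = epoch,
                   mcc_c = mcc[["c"]])
    }
  }

  history <- if (config$n_epochs > 0L) do.call(rbind, hist_rows) else
    data.frame(epoch = integer(0), tf = numeric(0),
               r_at = numeric(0), r_pt = numeric(0), r_c = numeric(0),
               r_v = numeric(0), mcc_at = numeric(0), mcc_pt = numeric(0),
               mcc_c = numeric(0), mcc_v = numeric(0))

  as_model <- function(w, c0, c1, n) {
    tab <- vocab
    tab$cw[match(keys, tab$key)] <- w
    semicor_model(tab, T = config$T, N = n, C0 = c0, C1 = c1)
  }
  final_model <- as_model(cw, C0, C1, config$n_epochs)
  if (is.null(best)) {
    model <- final_model
    chosen <- config$n_epochs
  } else {
    model <- as_model(best$cw, best$C0, best$C1, best$epoch)
    chosen <- best$epoch
  }
  structure(list(model = model, final_model = final_model,
                 history = history, chosen_epoch = chosen,
                 vocabulary_size = V, config = config),
            class = "mc_fit")
}

#' @export
print.mc_fit <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo fit (%s): %d epochs over %d non-rare attributes\n",
    x$config$target, x$config$n_epochs, x$vocabulary_size))
  cat(sprintf("  chosen epoch (calibration-MCC peak): %d\n", x$chosen_epoch))
  if (nrow(x$history)) {
    h <- x$history[x$history$epoch == x$chosen_epoch, ]
    cat(sprintf("  MCC at chosen epoch: AT %.3f / PT %.3f / C %.3f / V %.3f\n",
                h$mcc_at, h$mcc_pt, h$mcc_c, h$mcc_v))
  }
  invisible(x)
}

#' Locate the overtraining onset in an epoch history
#'
#' The calibration set exists to detect overtraining: its quality rises,
#' peaks, then declines while training quality keeps improving.  The best
#' epoch is the argmax of the calibration-set MCC; ties resolve to the
#' earliest epoch.
#'
#' @param history Epoch-history data frame from [mc_optimize()] (needs an
#'   \code{mcc_c} column).
#' @return Integer epoch number of the calibration peak.
#' @export
detect_overtraining <- function(history) {
  if (!is.data.frame(history) || nrow(history) == 0L)
    stop("non-empty history required")
  history$epoch[which.max(history$mcc_c)]
}

#' Plot epoch histories of the four sets
#'
#' MCC (or correlation) trajectories for active training, passive training,
#' calibration and validation across epochs, with the chosen epoch marked.
#'
#' @param x An \code{"mc_fit"}.
#' @param what \code{"mcc"} or \code{"r"}.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_history <- function(x, what = c("mcc", "r"), ...) {
  stopifnot(inherits(x, "mc_fit"), nrow(x$history) > 0L)
  what <- match.arg(what)
  cols <- paste0(what, c("_at", "_pt", "_c", "_v"))
  graphics::matplot(x$history$epoch, x$history[cols], type = "l", lty = 1,
                    col = c("grey40", "grey70", "firebrick", "steelblue"),
                    xlab = "epoch", ylab = toupper(what), ...)
  graphics::abline(v = x$chosen_epoch, lty = 3)
  graphics::legend("bottomright",
                   c("active training", "passive training",
                     "calibration", "validation"),
                   lty = 1, col = c("grey40", "grey70", "firebrick",
                                    "steelblue"), bty = "n")
  invisible(x)
}
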