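#' Simulate a labeled SMILES-like compound table with planted effects
#'
#' Generates random token strings over a SMILES-style alphabet and labels
#' them from a planted linear structure-activity signal: each compound's
#' true score is the sum of planted per-token weights over its single-token
#' attributes plus Gaussian noise.  Labels come either from thresholding
#' the score at the empirical quantile that realises the target active
#' fraction, or from a Bernoulli draw with logistic probability.  This
#' stands in for unavailable real endpoint tables (e.g. hepatotoxicity
#' panels of ~1300 drugs) so the whole pipeline is testable end to end;
#' the strings are not required to be chemically valid.
#'
#' Defaults emulate a DILI-scale study: 1274 compounds, ~60% active,
#' moderate noise, signal carried by five single tokens.
#'
#' @param n_compounds Number of compounds.
#' @param alphabet Token alphabet (must be tokens of the lexer dialect, so
#'   every generated string round-trips through [smiles_tokenize()]).
#' @param length_range Integer pair: tokens per compound drawn uniformly in
#'   this range.
#' @param planted_weights Named numeric vector: per-token contribution to
#'   the true score (names must be alphabet tokens).  All-zero weights with
#'   \code{label_rule = "threshold"} give pure-noise labels (a null
#'   dataset) provided \code{noise_sd > 0}.
#' @param noise_sd Standard deviation of the Gaussian noise on the score.
#' @param label_rule \code{"threshold"} (quantile cut, exact-ish fraction)
#'   or \code{"logistic"} (Bernoulli with logistic probability centred at
#'   the same quantile).
#' @param active_fraction Target fraction of active (label 1) compounds.
#' @param seed Integer seed (a dedicated sub-stream is derived from it).
#' @return Data frame with columns \code{smiles}, \code{label},
#'   \code{true_score}; the generator settings are attached as attribute
#'   \code{"generator_config"}.
#' @export
simulate_compounds <- function(n_compounds = 1274L,
                               alphabet = c("C", "c", "N", "O", "S", "Cl",
                                            "Br", "=", "#", "(", ")",
                                            "1", "2"),
                               length_range = c(10L, 30L),
                               planted_weights = c(N = 0.8, O = -0.8,
                                                   Cl = 1.2, S = -1.0,
                                                   "#" = 0.6),
                               noise_sd = 0.2,
                               label_rule = c("threshold", "logistic"),
                               active_fraction = 0.6,
                               seed = 1L) {
  label_rule <- match.arg(label_rule)
  n <- as.integer(n_compounds)
  stopifnot(n >= 1L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[1] <= length_range[2],
            noise_sd >= 0, active_fraction > 0, active_fraction < 1)
  if (length(planted_weights) &&
      !all(names(planted_weights) %in% alphabet))
    stop("planted_weights names must be alphabet tokens")

  set.seed(derive_seed(seed, "synthetic"))
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  toks <- lapply(lens, function(m) sample(alphabet, m, replace = TRUE))
  smiles <- vapply(toks, paste0, "", collapse = "")
  w <- planted_weights
  signal <- vapply(toks, function(tt) {
    if (!length(w)) return(0)
    sum(w[match(tt, names(w))], na.rm = TRUE)
  }, numeric(1))
  score <- signal + stats::rnorm(n, 0, noise_sd)
  if (length(unique(score)) == 1L)
    stop("unreachable active fraction: all true scores identical ",
         "(degenerate weights and zero noise)")
  cut <- stats::quantile(score, 1 - active_fraction, names = FALSE)
  label <- switch(label_rule,
    threshold = as.integer(score >= cut),
    logistic = stats::rbinom(n, 1L, stats::plogis(score - cut)))
  out <- data.frame(smiles = smiles, label = label, true_score = score,
                    stringsAsFactors = FALSE)
  attr(out, "generator_config") <- list(
    n_compounds = n, alphabet = alphabet, length_range = length_range,
    planted_weights = planted_weights, noise_sd = noise_sd,
    label_rule = label_rule, active_fraction = active_fraction, seed = seed)
  out
}
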