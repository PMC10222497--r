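# Shared fixtures for the semicor test suite.

# Planted-signal benchmark dataset: generator defaults at n = 400 with
# noise_sd = 0.2 (the parameter-recovery study conditions).
planted_data <- function(seed, n = 400L) {
  simulate_compounds(n_compounds = n, noise_sd = 0.2, seed = seed)
}

# Null dataset: no structure-activity signal, labels are thresholded noise.
null_data <- function(seed, n = 400L) {
  simulate_compounds(n_compounds = n, planted_weights = c(C = 0),
                     noise_sd = 0.2, seed = seed)
}

# Benchmark optimizer settings for the synthetic alphabet (see the methods
# vignette): T = 40 keeps attributes present in >= 40% of the ~100
# active-training compounds — with 13 tokens that is the single-token
# attributes, matching where the generator plants its signal.
bench_config <- function(seed, target = "TF1", n_epochs = 300L) {
  optimizer_config(target = target, T = 40L, n_epochs = n_epochs,
                   step = 1.0, seed = seed)
}

# Validation MCC of the returned (calibration-peak) model.
val_mcc <- function(fit) fit$history$mcc_v[fit$chosen_epoch]

fit_on_split1 <- function(data, config) {
  split <- make_splits(nrow(data), k = 1L, seed = config$seed)[[1]]
  mc_optimize(data, split, config)
}

# Hand-tokenized fixture: each string with its expected token sequence.
token_fixture <- list(
  list(s = "C=O",          t = c("C", "=", "O")),
  list(s = "ClCCl",        t = c("Cl", "C", "Cl")),
  list(s = "C%11CC%11",    t = c("C", "%11", "C", "C", "%11")),
  list(s = "BrCBr",        t = c("Br", "C", "Br")),
  list(s = "[N+](=O)[O-]", t = c("[N+]", "(", "=", "O", ")", "[O-]")),
  list(s = "[Cu]",         t = c("[Cu]")),
  list(s = "C[C@@H](N)O",  t = c("C", "[C@@H]", "(", "N", ")", "O")),
  list(s = "N#Cc1ccccc1",  t = c("N", "#", "C", "c", "1", "c", "c", "c",
                                 "c", "c", "1")),
  list(s = "CC(=O)Oc1ccccc1C(=O)O",
       t = c("C", "C", "(", "=", "O", ")", "O", "c", "1", "c", "c", "c",
             "c", "c", "1", "C", "(", "=", "O", ")", "O")),
  list(s = "O=S(=O)(N)c1ccc(Cl)cc1",
       t = c("O", "=", "S", "(", "=", "O", ")", "(", "N", ")", "c", "1",
             "c", "c", "c", "(", "Cl", ")", "c", "c", "1")),
  list(s = "C@@C",         t = c("C", "@@", "C")),
  list(s = "c1ccc2ccccc2c1",
       t = c("c", "1", "c", "c", "c", "2", "c", "c", "c", "c", "c", "2",
             "c", "1")),
  list(s = "FC(F)(F)Br",   t = c("F", "C", "(", "F", ")", "(", "F", ")",
                                 "Br")),
  list(s = "C1=CC=CS1",    t = c("C", "1", "=", "C", "C", "=", "C", "S",
                                 "1")),
  list(s = "[13CH4]",      t = c("[13CH4]")),
  list(s = "Clc1ccccc1%99C",
       t = c("Cl", "c", "1", "c", "c", "c", "c", "c", "1", "%99", "C")),
  list(s = "N=C=O",        t = c("N", "=", "C", "=", "O")),
  list(s = "CCl",          t = c("C", "Cl")),
  list(s = "lC",           t = c("l", "C")),   # lone 'l' is a plain char
  list(s = "CN(C)C(=N)N=C(N)N",
       t = c("C", "N", "(", "C", ")", "C", "(", "=", "N", ")", "N", "=",
             "C", "(", "N", ")", "N"))
)
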