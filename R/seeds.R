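# Seed fan-out: all randomness in the package flows from one top-level
# integer seed, with named sub-streams (split/init/moves/synthetic) derived
# deterministically so components can be re-run in isolation.
derive_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(what))
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}
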