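# Per-stage random streams.
#
# Every stochastic step (SAM permutations, synthetic generation) derives its
# own seed from the root seed plus a stage label, so adding or re-ordering a
# stage never perturbs another stage's draws, and a whole run is reproducible
# from the single root seed.

# Deterministic 31-bit hash of root seed + stage label (exact in doubles).
.stageSeed <- function(seed, stage) {
    h <- as.numeric(seed) %% 2147483647
    for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
    as.integer(h)
}

# Evaluate `code` under the derived stream, restoring the caller's RNG state.
.withStageSeed <- function(seed, stage, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(.stageSeed(seed, stage))
    code
}
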