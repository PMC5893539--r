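# Run expr with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is untouched.
.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    eval.parent(substitute(expr))
}

# Canonical unordered-pair key
.pairKey <- function(a, b) {
    ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}
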