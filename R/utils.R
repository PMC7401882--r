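# data.table used via :: only; declare awareness for [.data.table dispatch
.datatable.aware <- TRUE

# Evaluate `expr` with a temporarily seeded RNG, restoring (or removing)
# the caller's .Random.seed afterwards so package randomness never leaks
# into or depends on global state.
with_rng <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}
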