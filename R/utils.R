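# Internal helpers.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never disturb the
# global random stream.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The four demographic groups used throughout.
group_levels <- function() {
  c("male_youth", "female_youth", "male_middle_aged", "female_middle_aged")
}

group_key <- function(gender, age_group) paste(gender, age_group, sep = "_")
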