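#' @keywords internal
"_PACKAGE"

# Canonical order of the twelve kinematic features. Everything downstream
# (generators, extractor, model, analysis, file formats) indexes columns by
# these names.
KINVAE_FEATURES <- c(
  "MeanSpeed", "MaxSpeed", "MinSpeed", "sdSpeed",
  "MeanAcceleration", "MaxAcceleration", "MinAcceleration", "sdAcceleration",
  "STH", "DC", "sdDC", "MeanLength"
)

#' Feature names used throughout the package
#'
#' Returns the canonical ordered names of the twelve kinematic features
#' computed per trajectory and averaged per task: four speed statistics
#' (screen units/s), four signed-acceleration statistics (screen units/s^2),
#' straightness STH (chord length over path length, dimensionless in
#' \[0,1\]), directional change DC and its SD (radians/s), and the mean path
#' length per task (screen units).
#'
#' @return Character vector of length 12.
#' @export
feature_names <- function() KINVAE_FEATURES

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed. Stage- and
#' unit-level substreams (one per participant/task, per CV fold, per
#' perturbation run, ...) are derived by mixing the master seed with string
#' and integer tags through a splitmix-style integer hash, so any stage can
#' be regenerated in isolation and cohorts are reproducible under partial
#' regeneration.
#'
#' @param master Integer master seed.
#' @param ... Further character or integer tags identifying the substream.
#' @return An integer in \[0, 2^31 - 2\] suitable for [set.seed()].
#' @export
substream_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (tag in list(...)) {
    if (is.character(tag)) {
      codes <- utf8ToInt(paste(tag, collapse = "|"))
    } else {
      codes <- as.numeric(tag)
    }
    for (v in codes) {
      # 64-bit-free mixing: keep everything below 2^53 via modular steps
      h <- (h * 48271 + (v %% m) + 11) %% m
      h <- (h * 69621) %% m
    }
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never clobbers user
# randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

stop_kinvae <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "kinvae_error")))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    stop_kinvae(
      sprintf(
        "`%s` must be a finite number %s %s (got %s)", name,
        if (strict) ">" else ">=", lower, paste(format(x), collapse = ",")
      ),
      "kinvae_invalid_config"
    )
  }
  invisible(x)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
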