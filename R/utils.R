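# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages (record simulation, train/test split, weight
#' initialisation, noise injection) draw their own seed from one master seed
#' through this mixer, so a whole experiment is reproducible end-to-end while
#' stages stay statistically independent.
#'
#' @param master integer master seed.
#' @param ... one or more integer offsets identifying the stage (stream id,
#'   replicate index, ...).
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
child_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  x <- as.double(master) %% m
  for (k in c(...)) {
    # one multiplicative-congruential step per offset (Park-Miller multiplier)
    x <- (x * 48271 + as.double(k) * 2654435761) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

# Run `expr` under a local RNG state seeded with `seed`; restores the caller's
# RNG state afterwards so library code never perturbs user-level randomness.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Postural class labels
#'
#' The four postural behaviour classes, in canonical order: `ST` (stable
#' standing), `AP` (antero-posterior instability), `ML` (medio-lateral
#' instability), `UNST` (general multidirectional instability).
#'
#' @return Character vector of the four class labels.
#' @export
sway_classes <- function() c("ST", "AP", "ML", "UNST")

# Named feature subsets: the full set and the two reduced sets in which the
# mandatory displacement ranges are kept and one dispersion feature is dropped.
.subset_features <- function(subset = c("all4", "cea3", "rms3")) {
  subset <- match.arg(subset)
  switch(subset,
    all4 = c("dapmax_m", "dmlmax_m", "cea_m2", "rms_m"),
    cea3 = c("dapmax_m", "dmlmax_m", "cea_m2"),
    rms3 = c("dapmax_m", "dmlmax_m", "rms_m")
  )
}
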