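#' Construct a strain community
#'
#' A strain set describes a community of `N` microbial strains living in the
#' D-dimensional microbiome-behavior space. Each strain `i` carries feature
#' coordinates `m_i` inside the unit ball (its resource optimum as a function
#' of host behavior), an effect magnitude `d_i >= 0` quantifying how strongly
#' it can modulate host behavior, and a constant per-step cost `c_i` of
#' producing that effect. Strains with `affecting = FALSE` have `d_i = 0` and
#' pay no cost. Strains flagged `behavior_independent` grow at a constant
#' rate regardless of host behavior (a robustness variant).
#'
#' @param features numeric matrix, one row per strain, columns are the
#'   coordinates in the unit ball (row Euclidean norms must be <= 1).
#' @param effect_magnitude non-negative numeric vector of effect magnitudes
#'   `d_i`; must be 0 for non-affecting strains.
#' @param cost non-negative numeric vector (recycled) of per-step costs
#'   `c_i`; must be 0 for non-affecting strains.
#' @param affecting logical vector (recycled) marking strains that feed back
#'   on host behavior.
#' @param behavior_independent logical vector (recycled) marking strains
#'   whose growth rate is a constant instead of behavior-dependent.
#' @return An object of class `mb_strains`.
#' @seealso [sample_strains()], [growth_rate()]
#' @export
strain_set <- function(features, effect_magnitude, cost = 0,
                       affecting = effect_magnitude > 0,
                       behavior_independent = FALSE) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  if (n < 1L) stop("at least one strain is required")
  norms <- sqrt(rowSums(features^2))
  if (any(norms > 1 + 1e-9))
    stop("strain feature coordinates must lie within the unit ball")
  effect_magnitude <- as.numeric(effect_magnitude)
  if (length(effect_magnitude) == 1L)
    effect_magnitude <- rep(effect_magnitude, n)
  cost <- rep_len(as.numeric(cost), n)
  affecting <- rep_len(as.logical(affecting), n)
  behavior_independent <- rep_len(as.logical(behavior_independent), n)
  if (length(effect_magnitude) != n)
    stop("effect_magnitude must have one value per strain")
  if (any(effect_magnitude < 0)) stop("effect magnitudes must be >= 0")
  if (any(cost < 0)) stop("costs must be >= 0")
  if (any(effect_magnitude[!affecting] != 0))
    stop("non-affecting strains must have effect magnitude 0")
  if (any(cost[!affecting] != 0))
    stop("non-affecting strains must have cost 0")
  structure(list(features = features,
                 effect_magnitude = effect_magnitude,
                 cost = cost,
                 affecting = affecting,
                 behavior_independent = behavior_independent),
            class = "mb_strains")
}

#' @export
print.mb_strains <- function(x, ...) {
  cat(sprintf("<mb_strains> %d strains in %d dimensions; %d affecting (mean d = %.3g)\n",
              nrow(x$features), ncol(x$features), sum(x$affecting),
              mean(x$effect_magnitude[x$affecting])))
  invisible(x)
}

#' Sample a random strain community
#'
#' Draws strain feature coordinates uniformly over the volume of the
#' D-dimensional unit ball (isotropic direction times a `u^(1/D)` radius
#' transform) and assigns effect magnitudes `d_i ~ Exponential(mean =
#' mean_effect)` to a fixed fraction of the strains; the remaining strains
#' are non-affecting (`d_i = 0`, zero cost). Uses the current RNG state, so
#' wrap in `set.seed()` for reproducibility.
#'
#' @param n number of strains (>= 1).
#' @param dims dimensionality of the feature space (>= 1; 2 in the standard
#'   scenarios).
#' @param mean_effect mean of the exponential distribution of effect
#'   magnitudes; 0 yields an effect-free community.
#' @param affecting_fraction proportion of strains (rounded to a count) that
#'   affect host behavior.
#' @param cost per-step cost applied to each affecting strain.
#' @param behavior_independent_fraction proportion of strains whose growth
#'   rate is held constant (robustness variant; default 0).
#' @return An [strain_set()] object.
#' @export
sample_strains <- function(n, dims = 2, mean_effect = 10,
                           affecting_fraction = 1, cost = 0,
                           behavior_independent_fraction = 0) {
  n <- as.integer(n)
  dims <- as.integer(dims)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (is.na(dims) || dims < 1L) stop("dims must be a positive integer")
  if (mean_effect < 0) stop("mean_effect must be >= 0")
  if (affecting_fraction < 0 || affecting_fraction > 1)
    stop("affecting_fraction must be in [0, 1]")
  z <- matrix(stats::rnorm(n * dims), nrow = n)
  dirn <- z / sqrt(rowSums(z^2))
  rad <- stats::runif(n)^(1 / dims)
  features <- dirn * rad
  n_aff <- round(n * affecting_fraction)
  affecting <- rep(FALSE, n)
  if (n_aff > 0) affecting[seq_len(n_aff)] <- TRUE
  d <- numeric(n)
  if (n_aff > 0 && mean_effect > 0)
    d[affecting] <- stats::rexp(n_aff, rate = 1 / mean_effect)
  costv <- numeric(n)
  costv[affecting] <- cost
  indep <- rep(FALSE, n)
  n_ind <- round(n * behavior_independent_fraction)
  if (n_ind > 0) indep[sample.int(n, n_ind)] <- TRUE
  strain_set(features, d, costv, affecting, indep)
}

#' Growth-function parameters
#'
#' The host-derived growth rate of a strain is
#' `r_i = floor + max(0, 1 - beta * dist(b, m_i)^alpha)`, a monotonically
#' decreasing function of the Euclidean distance between the host behavior
#' `b` and the strain's features `m_i`. With the defaults (`alpha = 3`,
#' `beta = 0.1`, `floor = 0.1`) and all points in the 2D unit ball, rates
#' range over [0.3, 1.1] for behavior on the unit segment.
#'
#' @param alpha positive exponent shaping the distance decay.
#' @param beta non-negative scale of the distance penalty; also the maximal
#'   growth advantage one strain can hold over another on the unit segment.
#' @param floor additive base rate granted regardless of distance.
#' @param r_independent constant growth rate used for strains flagged
#'   `behavior_independent` (default 0.6, the midpoint of the attainable
#'   2D range).
#' @return An object of class `mb_growth_params`.
#' @export
growth_params <- function(alpha = 3, beta = 0.1, floor = 0.1,
                          r_independent = 0.6) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  structure(list(alpha = alpha, beta = beta, floor = floor,
                 r_independent = r_independent),
            class = "mb_growth_params")
}

#' Host-derived growth rates
#'
#' Evaluates `r_i = floor + max(0, 1 - beta * ||b - m_i||^alpha)` for every
#' strain; strains flagged behavior-independent receive the constant
#' `params$r_independent`.
#'
#' @param behavior numeric behavior coordinate vector (length must equal the
#'   strain feature dimensionality).
#' @param strains an [strain_set()] object.
#' @param params an [growth_params()] object.
#' @return Numeric vector of growth rates, one per strain.
#' @export
growth_rate <- function(behavior, strains, params = growth_params()) {
  behavior <- as.numeric(behavior)
  if (any(!is.finite(behavior))) stop("behavior must be finite")
  if (length(behavior) != ncol(strains$features))
    stop("behavior dimensionality does not match strain features")
  dist <- sqrt(colSums((t(strains$features) - behavior)^2))
  r <- params$floor + pmax(0, 1 - params$beta * dist^params$alpha)
  r[strains$behavior_independent] <- params$r_independent
  r
}

#' Write / read a strain community as TSV
#'
#' The table holds one row per strain (coordinates, effect magnitude, cost
#' and flags); a JSON sidecar `<path>.json` records sampling metadata so a
#' community can be traced back to the parameters that generated it.
#'
#' @param strains an [strain_set()] object.
#' @param path TSV file path.
#' @param meta named list of metadata (e.g. seed and sampling parameters)
#'   stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_strains <- function(strains, path, meta = list()) {
  feat <- strains$features
  colnames(feat) <- paste0("m", seq_len(ncol(feat)))
  df <- data.frame(feat,
                   effect_magnitude = strains$effect_magnitude,
                   cost = strains$cost,
                   affecting = strains$affecting,
                   behavior_independent = strains$behavior_independent)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_strains
#' @export
read_strains <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  mcols <- grep("^m[0-9]+$", names(df), value = TRUE)
  strain_set(as.matrix(df[mcols]),
             effect_magnitude = df$effect_magnitude,
             cost = df$cost,
             affecting = df$affecting,
             behavior_independent = df$behavior_independent)
}
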