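#' Parameters of a synthetic digitizer leaf
#'
#' Describes one parametric maize ear leaf in digitizer-grid form. The
#' midvein is an arc-length parameterized circular bend of total length
#' `length_cm`; at `n_transects` evenly spaced stations five points are
#' placed across the local width, to which twist, margin waves (columns 1
#' and 5) and a transverse fold field concentrated in the lower-middle
#' region are applied; a single tip point completes the `5n + 1` grid.
#' With all deformations zero the generated surface is exactly planar.
#'
#' @param length_cm midvein arc length (cm).
#' @param max_width_cm maximum leaf width (cm).
#' @param widest_frac relative midvein position of the maximum width,
#'   in (0, 1).
#' @param bend_curvature midvein bend (rad per cm).
#' @param twist_total cumulative twist from base to tip (rad).
#' @param wave_amp,wave_freq margin waviness amplitude (cm) and frequency
#'   (cycles along the leaf).
#' @param fold_amp,fold_freq transverse surface-fold amplitude (cm) and
#'   frequency across the blade.
#' @param n_transects number of transects (>= 2).
#' @param jitter_cm isotropic point noise emulating digitizer precision.
#' @param seed integer RNG seed making the leaf deterministic.
#' @return object of class `leaf_params`.
#' @export
leaf_params <- function(length_cm = 75, max_width_cm = 9, widest_frac = 0.4,
                        bend_curvature = 0.02, twist_total = 0.15,
                        wave_amp = 0.15, wave_freq = 3,
                        fold_amp = 0.1, fold_freq = 2,
                        n_transects = 13L, jitter_cm = 0, seed = 1L) {
  stopifnot(length_cm > 0, max_width_cm > 0,
            widest_frac > 0, widest_frac < 1, n_transects >= 2L,
            wave_amp >= 0, fold_amp >= 0, jitter_cm >= 0)
  if (fold_amp > 0.25 * max_width_cm)
    stop("rejected: fold_amp too large (self-intersection risk)")
  if (wave_amp > 0.25 * max_width_cm)
    stop("rejected: wave_amp too large (self-intersection risk)")
  structure(list(length_cm = length_cm, max_width_cm = max_width_cm,
                 widest_frac = widest_frac, bend_curvature = bend_curvature,
                 twist_total = twist_total, wave_amp = wave_amp,
                 wave_freq = wave_freq, fold_amp = fold_amp,
                 fold_freq = fold_freq, n_transects = as.integer(n_transects),
                 jitter_cm = jitter_cm, seed = as.integer(seed)),
            class = "leaf_params")
}

## Width profile: beta-shaped polynomial (t + d)^a (1 - t)^b, normalized
## to its maximum which falls at widest_frac; positive at the base.
width_profile <- function(t, widest_frac, d = 0.25, b = 2) {
  a <- b * (widest_frac + d) / (1 - widest_frac)
  p <- (t + d)^a * (1 - t)^b
  p / ((widest_frac + d)^a * (1 - widest_frac)^b)
}

with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic digitizer leaf
#'
#' @param params a [leaf_params()].
#' @return a [digitized_leaf()] obeying the `5n + 1` point-count rule.
#' @export
generate_leaf <- function(params) {
  stopifnot(inherits(params, "leaf_params"))
  with_local_seed(params$seed, {
    p <- params
    n <- p$n_transects
    phase_l <- stats::runif(1, 0, 2 * pi)
    phase_r <- stats::runif(1, 0, 2 * pi)
    phase_f <- stats::runif(1, 0, 2 * pi)
    tt <- (seq_len(n) - 1) / n            # transect stations; tip at t = 1
    s <- tt * p$length_cm
    b <- p$bend_curvature
    arc <- function(sv) {
      if (abs(b) < 1e-12) cbind(sv, 0, 0)
      else cbind(sin(b * sv) / b, 0, (1 - cos(b * sv)) / b)
    }
    P <- arc(s)
    Tg <- cbind(cos(b * s), 0, sin(b * s))       # tangent
    N0 <- cbind(-sin(b * s), 0, cos(b * s))      # surface normal (no twist)
    B0 <- matrix(rep(c(0, 1, 0), each = n), n, 3)
    psi <- p$twist_total * tt
    Bv <- cos(psi) * B0 + sin(psi) * N0
    Nv <- -sin(psi) * B0 + cos(psi) * N0
    w <- p$max_width_cm * width_profile(tt, p$widest_frac)
    offs <- c(-0.5, -0.25, 0, 0.25, 0.5)
    env <- exp(-((tt - 0.35) / 0.25)^2)          # lower-middle fold focus
    tr <- array(0, dim = c(n, 5L, 3L))
    for (k in 1:5) {
      lat <- w * offs[k]
      normal_disp <- p$fold_amp * env *
        sin(pi * p$fold_freq * 2 * offs[k] + 2 * pi * tt + phase_f)
      if (k == 1L)
        normal_disp <- normal_disp +
          p$wave_amp * sin(2 * pi * p$wave_freq * tt + phase_l)
      if (k == 5L)
        normal_disp <- normal_disp +
          p$wave_amp * sin(2 * pi * p$wave_freq * tt + phase_r)
      tr[, k, ] <- P + lat * Bv + normal_disp * Nv
    }
    tip <- as.numeric(arc(p$length_cm))
    if (p$jitter_cm > 0) {
      tr <- tr + array(stats::rnorm(length(tr), 0, p$jitter_cm), dim = dim(tr))
      tip <- tip + stats::rnorm(3, 0, p$jitter_cm)
    }
    digitized_leaf(tr, tip)
  })
}

#' Specification of a synthetic inbred-line population
#'
#' Line-level parameters are drawn uniformly from the stated ranges
#' (matching a maize ear-leaf population at silking: lengths 60-95 cm,
#' widths 6-12 cm, 13-18 transects so grids hold 66-91 points, gentle
#' bend up to 0.05 rad/cm, twist up to 0.3 rad, folds up to 2% of width);
#' replicates within a line perturb each parameter with Gaussian noise
#' whose standard deviation is `noise_ratio` times the between-line
#' standard deviation of that parameter.
#'
#' @param n_lines number of inbred lines.
#' @param replicates samples per line (1-3).
#' @param noise_ratio within-line / between-line spread ratio.
#' @param master_seed master RNG seed; every leaf derives its own seed
#'   from (master, line, replicate).
#' @param jitter_cm digitizer point noise per leaf (cm).
#' @param ranges named list of `c(lo, hi)` line-parameter ranges.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_lines = 100L, replicates = 3L,
                            noise_ratio = 0.15, master_seed = 1L,
                            jitter_cm = 0.02,
                            ranges = list(
                              length_cm = c(60, 95),
                              max_width_cm = c(6, 12),
                              widest_frac = c(0.30, 0.50),
                              bend_curvature = c(0.005, 0.05),
                              twist_total = c(-0.3, 0.3),
                              wave_amp = c(0, 0.3),
                              wave_freq = c(2, 4),
                              fold_frac = c(0, 0.02),
                              fold_freq = c(1, 3),
                              n_transects = c(13, 18))) {
  stopifnot(n_lines >= 1L, replicates >= 1L, replicates <= 3L,
            noise_ratio >= 0)
  structure(list(n_lines = as.integer(n_lines),
                 replicates = as.integer(replicates),
                 noise_ratio = noise_ratio,
                 master_seed = as.integer(master_seed),
                 jitter_cm = jitter_cm, ranges = ranges),
            class = "population_spec")
}

derive_seed <- function(master, line, rep) {
  as.integer((1664525 * ((master %% 65536) + 1000003 * line + 7919 * rep) +
              1013904223) %% 2147483647)
}

#' Generate a synthetic leaf population with ground truth
#'
#' @param spec a [population_spec()].
#' @return list with `leaves` (list of [digitized_leaf()]s, line/sample
#'   ids set) and `truth` (data frame of the true line-level parameters).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  rg <- spec$ranges
  leaves <- vector("list", spec$n_lines * spec$replicates)
  truth <- vector("list", spec$n_lines)
  idx <- 0L
  for (l in seq_len(spec$n_lines)) {
    line_id <- sprintf("L%03d", l)
    lp <- with_local_seed(derive_seed(spec$master_seed, l, 0L), {
      draw <- function(nm) stats::runif(1, rg[[nm]][1], rg[[nm]][2])
      list(length_cm = draw("length_cm"),
           max_width_cm = draw("max_width_cm"),
           widest_frac = draw("widest_frac"),
           bend_curvature = draw("bend_curvature"),
           twist_total = draw("twist_total"),
           wave_amp = draw("wave_amp"),
           wave_freq = draw("wave_freq"),
           fold_frac = draw("fold_frac"),
           fold_freq = draw("fold_freq"),
           n_transects = sample(rg$n_transects[1]:rg$n_transects[2], 1))
    })
    truth[[l]] <- data.frame(line_id = line_id, as.data.frame(lp),
                             stringsAsFactors = FALSE)
    for (r in seq_len(spec$replicates)) {
      seed_lr <- derive_seed(spec$master_seed, l, r)
      rp <- with_local_seed(seed_lr, {
        jig <- function(nm, lo_ok = -Inf, hi_ok = Inf) {
          sd_between <- (rg[[nm]][2] - rg[[nm]][1]) / sqrt(12)
          clamp(lp[[nm]] + stats::rnorm(1, 0, spec$noise_ratio * sd_between),
                lo_ok, hi_ok)
        }
        list(length_cm = jig("length_cm", 5),
             max_width_cm = jig("max_width_cm", 0.5),
             widest_frac = jig("widest_frac", 0.05, 0.95),
             bend_curvature = jig("bend_curvature"),
             twist_total = jig("twist_total"),
             wave_amp = jig("wave_amp", 0),
             wave_freq = jig("wave_freq", 0.5),
             fold_frac = jig("fold_frac", 0),
             fold_freq = jig("fold_freq", 0.5))
      })
      params <- leaf_params(
        length_cm = rp$length_cm, max_width_cm = rp$max_width_cm,
        widest_frac = rp$widest_frac, bend_curvature = rp$bend_curvature,
        twist_total = rp$twist_total, wave_amp = rp$wave_amp,
        wave_freq = rp$wave_freq,
        fold_amp = rp$fold_frac * rp$max_width_cm,
        fold_freq = rp$fold_freq, n_transects = lp$n_transects,
        jitter_cm = spec$jitter_cm, seed = seed_lr)
      leaf <- generate_leaf(params)
      leaf$line_id <- line_id
      leaf$sample_id <- sprintf("%s_R%d", line_id, r)
      idx <- idx + 1L
      leaves[[idx]] <- leaf
    }
  }
  list(leaves = leaves, truth = do.call(rbind, truth))
}
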