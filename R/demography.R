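#' Define a demographic epoch
#'
#' An epoch is one piece of a piecewise demographic history, described going
#' backwards in time from its recent end. Within an epoch the diploid
#' effective size at `s` generations past the epoch's recent boundary is
#' `N(s) = start_size * exp(-growth_rate * s)`, so a positive `growth_rate`
#' means the population has been growing towards the present.
#'
#' @param duration Epoch length in generations; `Inf` is allowed only for the
#'   most ancient epoch.
#' @param start_size Diploid effective population size at the epoch's recent
#'   end (must be positive).
#' @param growth_rate Per-generation exponential growth rate towards the
#'   present; 0 means constant size within the epoch. An infinite epoch must
#'   have rate 0.
#' @return An object of class `"epoch"`.
#' @seealso [demographic_model()]
#' @export
epoch <- function(duration, start_size, growth_rate = 0) {
  stopifnot(is.numeric(duration), length(duration) == 1L,
            is.numeric(start_size), length(start_size) == 1L,
            is.numeric(growth_rate), length(growth_rate) == 1L)
  if (!(duration > 0)) stop("epoch duration must be positive (or Inf)")
  if (!(start_size > 0) || !is.finite(start_size)) {
    stop("epoch start_size must be positive and finite")
  }
  if (is.infinite(duration) && growth_rate != 0) {
    stop("an infinite epoch must have growth_rate = 0")
  }
  structure(list(duration = duration, start_size = start_size,
                 growth_rate = growth_rate), class = "epoch")
}

#' Define a piecewise demographic model
#'
#' Epochs are listed from the present backwards into the past; the most
#' ancient epoch must have infinite duration so that the coalescent process
#' always terminates. The mutation rate enters only statistics where
#' `theta = 4*N*mu` matters (expected counts); all scale-free statistics
#' (normalized spectra, the burden of private mutations) are invariant to
#' jointly rescaling all sizes and durations.
#'
#' @param epochs List of [epoch()] objects, present to past. The last (and
#'   only the last) epoch may be infinite; a finite last epoch is extended to
#'   infinity at its final size with a warning.
#' @param mutation_rate Per-site per-generation mutation rate `mu` (optional;
#'   only needed where `theta` matters).
#' @param label Free-text model label.
#' @return An object of class `"demographic_model"`.
#' @examples
#' m <- demographic_model(list(epoch(Inf, 1e4)), label = "constant")
#' cumulative_coalescent_rate(m, 2e4)  # = 1 coalescent intensity unit
#' @export
demographic_model <- function(epochs, mutation_rate = NULL, label = "") {
  if (inherits(epochs, "epoch")) epochs <- list(epochs)
  stopifnot(is.list(epochs), length(epochs) >= 1L)
  if (!all(vapply(epochs, inherits, logical(1), "epoch"))) {
    stop("'epochs' must be a list of epoch() objects")
  }
  k <- length(epochs)
  dur <- vapply(epochs, `[[`, numeric(1), "duration")
  if (any(is.infinite(dur[-k]))) {
    stop("only the most ancient epoch may have infinite duration")
  }
  if (is.finite(dur[k])) {
    warning("extending the most ancient epoch to infinite duration at its ",
            "final size")
    last <- epochs[[k]]
    n_end <- last$start_size * exp(-last$growth_rate * last$duration)
    epochs[[k + 1L]] <- epoch(Inf, n_end, 0)
  }
  if (!is.null(mutation_rate)) {
    stopifnot(is.numeric(mutation_rate), mutation_rate > 0)
  }
  structure(list(epochs = epochs, mutation_rate = mutation_rate,
                 label = label), class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "with", length(x$epochs), "epoch(s) (present -> past):\n")
  for (e in x$epochs) {
    cat(sprintf("  duration %s gen, N = %g%s\n",
                format(e$duration), e$start_size,
                if (e$growth_rate != 0)
                  sprintf(", growth %.4g/gen", e$growth_rate) else ""))
  }
  invisible(x)
}

# Epoch table used by the numerical routines: start time of each epoch
# (generations before present), per-epoch intensity increment, and the
# cumulative intensity at each epoch's recent boundary.
.epoch_table <- function(model) {
  eps <- model$epochs
  dur <- vapply(eps, `[[`, numeric(1), "duration")
  n0 <- vapply(eps, `[[`, numeric(1), "start_size")
  g <- vapply(eps, `[[`, numeric(1), "growth_rate")
  # intensity accumulated across one whole epoch: int_0^d ds / (2 N(s))
  dlam <- ifelse(g == 0, dur / (2 * n0), expm1(g * dur) / (2 * n0 * g))
  t0 <- cumsum(c(0, dur[-length(dur)]))
  lam0 <- cumsum(c(0, dlam[-length(dlam)]))
  list(t0 = t0, dur = dur, n0 = n0, g = g, dlam = dlam, lam0 = lam0)
}

#' Cumulative coalescent intensity of a demographic model
#'
#' Computes the dimensionless coalescent intensity
#' `Lambda(t) = integral_0^t ds / (2 N(s))` at `t` generations before the
#' present. A single pair of lineages coalesces by time `t` with probability
#' `1 - exp(-Lambda(t))`; `Lambda` is the time change that maps the
#' variable-size coalescent onto the standard one.
#'
#' @param model A [demographic_model()].
#' @param t Time in generations before present (vectorized, each `>= 0`).
#' @return Numeric vector of intensities; strictly increasing in `t`, with
#'   `Lambda(0) = 0`.
#' @export
cumulative_coalescent_rate <- function(model, t) {
  stopifnot(inherits(model, "demographic_model"), is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  tab <- .epoch_table(model)
  i <- findInterval(t, tab$t0, rightmost.closed = FALSE)  # epoch index >= 1
  s <- t - tab$t0[i]
  within <- ifelse(tab$g[i] == 0, s / (2 * tab$n0[i]),
                   expm1(tab$g[i] * s) / (2 * tab$n0[i] * tab$g[i]))
  unname(tab$lam0[i] + within)
}

# Inverse of the cumulative intensity: real time (generations) at which the
# intensity reaches u. Used by the Monte-Carlo coalescent simulator.
.inverse_intensity <- function(model, u) {
  tab <- .epoch_table(model)
  brk <- tab$lam0
  i <- findInterval(u, brk, rightmost.closed = FALSE)
  du <- u - tab$lam0[i]
  s <- ifelse(tab$g[i] == 0, du * 2 * tab$n0[i],
              log1p(du * 2 * tab$n0[i] * tab$g[i]) / tab$g[i])
  unname(tab$t0[i] + s)
}

#' Preset demographic models
#'
#' Returns three named models spanning the histories commonly contrasted when
#' studying rare-variant burdens: (i) constant population size; (ii) a
#' two-bottleneck history without recent growth; (iii) the same bottleneck
#' history followed by a terminal epoch of rapid exponential growth (a few
#' percent per generation, as estimated for European populations). The
#' bottleneck and growth parameter values are illustrative toy settings, not
#' fitted values from any published demographic inference; users wanting a
#' specific published history should build it with [demographic_model()] or
#' load it from a config file via [read_model_config()].
#'
#' @param n_anc Ancestral/baseline diploid size (default 10000).
#' @param growth_rate Per-generation growth rate of the terminal epoch of the
#'   growth model (default 0.035, within the 2--5\% per-generation range
#'   estimated for recent European growth).
#' @param growth_duration Duration of the growth epoch in generations
#'   (default 120).
#' @return Named list of [demographic_model()] objects:
#'   `constant`, `bottleneck_toy`, `growth_toy`.
#' @export
preset_models <- function(n_anc = 10000, growth_rate = 0.035,
                          growth_duration = 120) {
  constant <- demographic_model(list(epoch(Inf, n_anc)), label = "constant")
  # two bottlenecks: a recent one and an out-of-Africa-like ancient one
  bneck <- list(epoch(920, n_anc),
                epoch(80, n_anc * 0.055),    # recent bottleneck
                epoch(2800, n_anc),
                epoch(200, n_anc * 0.12),    # ancient bottleneck
                epoch(Inf, n_anc * 1.4))
  bottleneck_toy <- demographic_model(bneck, label = "bottleneck_toy")
  n_pre_growth <- bneck[[1]]$start_size
  n_now <- n_pre_growth * exp(growth_rate * growth_duration)
  growth <- c(list(epoch(growth_duration, n_now, growth_rate),
                   epoch(920 - growth_duration, n_pre_growth)),
              bneck[-1])
  growth_toy <- demographic_model(growth, label = "growth_toy")
  list(constant = constant, bottleneck_toy = bottleneck_toy,
       growth_toy = growth_toy)
}

#' Read or write a demographic model config (JSON or YAML)
#'
#' The config format has keys `epochs` (list of `{duration, start_size,
#' growth_rate}`, present to past; `duration: "Inf"` or a missing duration on
#' the last epoch means infinite), optional `mutation_rate`, and optional
#' `label`. The format is chosen by file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path File path.
#' @return `read_model_config()` returns a [demographic_model()];
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  if (is.null(cfg$epochs)) stop("config has no 'epochs' key")
  eps <- lapply(cfg$epochs, function(e) {
    dur <- e$duration
    if (is.null(dur) || identical(dur, "Inf")) dur <- Inf
    epoch(as.numeric(dur), as.numeric(e$start_size),
          if (is.null(e$growth_rate)) 0 else as.numeric(e$growth_rate))
  })
  demographic_model(eps, mutation_rate = cfg$mutation_rate,
                    label = if (is.null(cfg$label)) "" else cfg$label)
}

#' @rdname read_model_config
#' @param model A [demographic_model()] to serialize.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "demographic_model"))
  eps <- lapply(model$epochs, function(e) {
    list(duration = if (is.infinite(e$duration)) "Inf" else e$duration,
         start_size = e$start_size, growth_rate = e$growth_rate)
  })
  cfg <- list(epochs = eps, mutation_rate = model$mutation_rate,
              label = model$label)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}
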