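#' Generate distinct coda-type rhythm templates
#'
#' A type template is the base ICI vector of a rhythmic coda pattern. The
#' generator draws templates until all pairs are at least `margin` apart in
#' normalized distance (templates compared at equal length are scaled to
#' unit mean; templates of different lengths are always considered distinct),
#' so the separation between classes is controllable.
#'
#' @param n_types Number of templates (>= 1).
#' @param length_range Length-2 integer range of ICI counts per template,
#'   within \[2, 11\].
#' @param seed Integer seed; templates are reproducible.
#' @param margin Minimum pairwise normalized distance between same-length
#'   templates.
#' @param ici_range Range of base ICI values in seconds.
#' @param max_tries Retry budget before giving up.
#' @return A named list of `type_template` objects (`name`, `base_icis`),
#'   names `T1..Tn`.
#' @export
make_type_templates <- function(n_types, length_range = c(3, 9), seed = 1L,
                                margin = 0.25, ici_range = c(0.1, 0.6),
                                max_tries = 1000L) {
  stopifnot(n_types >= 1, length(length_range) == 2L,
            length_range[1] >= 2, length_range[2] <= 11,
            length_range[1] <= length_range[2], margin >= 0)
  set.seed(seed)
  norm_dist <- function(a, b) {
    if (length(a) != length(b)) return(Inf)
    sqrt(mean((a / mean(a) - b / mean(b))^2))
  }
  templates <- list()
  tries <- 0L
  while (length(templates) < n_types) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not draw ", n_types, " templates with margin ", margin,
           " in ", max_tries, " tries; lower the margin")
    }
    len <- if (length_range[1] == length_range[2]) length_range[1] else
      sample(length_range[1]:length_range[2], 1L)
    cand <- stats::runif(len, ici_range[1], ici_range[2])
    ok <- all(vapply(templates, function(tp)
      norm_dist(tp$base_icis, cand) >= margin, logical(1)))
    if (ok) {
      nm <- paste0("T", length(templates) + 1L)
      templates[[nm]] <- structure(list(name = nm, base_icis = cand),
                                   class = "type_template")
    }
  }
  templates
}

#' Specification of a synthetic coda population
#'
#' Encodes the hierarchical structure that the annotation labels assume:
#' coda types are rhythm templates; vocal clans differ in which types they
#' use (a usage distribution over templates) and in overall tempo; and
#' individual whales belong to one clan and carry a personal tempo offset.
#' Each generated coda is its template scaled by the clan tempo, the whale
#' tempo, and i.i.d. multiplicative lognormal jitter of coefficient of
#' variation `jitter_cv` (mean 1, so jitter never changes the expected
#' tempo and ICIs stay positive).
#'
#' @param templates Named list from [make_type_templates()].
#' @param clans Named list: each element a list with `usage` (named
#'   probability vector over template names, summing to 1) and `tempo`
#'   (positive factor).
#' @param whales Named list: each element a list with `clan` (a name in
#'   `clans`) and `tempo` (positive factor).
#' @param jitter_cv Coefficient of variation of the multiplicative ICI
#'   jitter (>= 0).
#' @param n_per_class Codas generated per class along `class_axis`.
#' @param class_axis `"type"`, `"clan"`, or `"whale"`: the axis along which
#'   `n_per_class` is enforced exactly.
#' @param seed Integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(templates, clans, whales, jitter_cv = 0.02,
                       n_per_class = 100, class_axis = c("type", "clan", "whale"),
                       seed = 1L) {
  class_axis <- match.arg(class_axis)
  stopifnot(length(templates) >= 1, length(clans) >= 1, length(whales) >= 1,
            jitter_cv >= 0, n_per_class >= 1)
  for (cl in clans) {
    stopifnot(abs(sum(cl$usage) - 1) < 1e-8, cl$tempo > 0,
              all(names(cl$usage) %in% names(templates)))
  }
  for (wh in whales) {
    stopifnot(wh$clan %in% names(clans), wh$tempo > 0)
  }
  structure(
    list(templates = templates, clans = clans, whales = whales,
         jitter_cv = jitter_cv, n_per_class = as.integer(n_per_class),
         class_axis = class_axis, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Build a simple fully specified synthetic population
#'
#' Convenience wrapper: `n_types` templates, `n_clans` clans with distinct
#' type-usage profiles (each clan concentrates on its own subset of types)
#' and tempos spread around 1, and `whales_per_clan` whales per clan with
#' individual tempo offsets.
#'
#' @param n_types Number of coda types.
#' @param n_clans Number of vocal clans.
#' @param whales_per_clan Whales per clan.
#' @param jitter_cv Multiplicative jitter coefficient of variation.
#' @param n_per_class Codas per class along `class_axis`.
#' @param class_axis See [synth_spec()].
#' @param seed Integer seed.
#' @param length_range Template ICI-count range.
#' @param margin Template separation margin.
#' @return A [synth_spec()].
#' @export
simple_synth_spec <- function(n_types = 5, n_clans = 2, whales_per_clan = 2,
                              jitter_cv = 0.02, n_per_class = 100,
                              class_axis = "type", seed = 1L,
                              length_range = c(3, 9), margin = 0.25) {
  templates <- make_type_templates(n_types, length_range = length_range,
                                   seed = seed, margin = margin)
  set.seed(seed + 1L)
  type_names <- names(templates)
  clans <- list()
  clan_tempos <- seq(0.85, 1.15, length.out = max(n_clans, 2))[seq_len(n_clans)]
  for (j in seq_len(n_clans)) {
    w <- rep(1, n_types)
    # each clan prefers a distinct block of types
    fav <- ((seq_len(n_types) - 1L) %% n_clans) == (j - 1L)
    w[fav] <- 6
    clans[[paste0("C", j)]] <- list(
      usage = stats::setNames(w / sum(w), type_names),
      tempo = clan_tempos[j]
    )
  }
  whales <- list()
  for (j in seq_len(n_clans)) {
    tempos <- seq(0.92, 1.08, length.out = max(whales_per_clan, 2))
    for (k in seq_len(whales_per_clan)) {
      whales[[paste0("W", j, "_", k)]] <-
        list(clan = paste0("C", j), tempo = tempos[k])
    }
  }
  synth_spec(templates, clans, whales, jitter_cv = jitter_cv,
             n_per_class = n_per_class, class_axis = class_axis, seed = seed)
}

#' Generate a synthetic coda dataset
#'
#' Draws `n_per_class` codas for each class along the configured axis. For
#' the type axis the producing whale is drawn uniformly; for the clan and
#' whale axes the coda's type is drawn from the clan's usage distribution.
#' ICIs are `template x clan tempo x whale tempo x jitter`, with mean-1
#' lognormal jitter of coefficient of variation `jitter_cv`. All three
#' labels are recorded on every coda.
#'
#' @param spec A [synth_spec()].
#' @return A [coda_dataset()] tagged `"synthetic"`.
#' @export
generate_codas <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  sigma <- sqrt(log(1 + spec$jitter_cv^2))
  mu <- -sigma^2 / 2
  whale_names <- names(spec$whales)
  jitter <- function(n) {
    if (spec$jitter_cv == 0) rep(1, n) else stats::rlnorm(n, mu, sigma)
  }
  make_one <- function(type_name, whale_name) {
    wh <- spec$whales[[whale_name]]
    cl <- spec$clans[[wh$clan]]
    base <- spec$templates[[type_name]]$base_icis
    coda(base * cl$tempo * wh$tempo * jitter(length(base)),
         type = type_name, clan = wh$clan, whale = whale_name,
         source = "synthetic")
  }
  codas <- list()
  if (spec$class_axis == "type") {
    for (tn in names(spec$templates)) {
      for (i in seq_len(spec$n_per_class)) {
        wn <- sample(whale_names, 1L)
        codas[[length(codas) + 1L]] <- make_one(tn, wn)
      }
    }
  } else if (spec$class_axis == "clan") {
    for (cn in names(spec$clans)) {
      members <- whale_names[vapply(spec$whales, function(w)
        w$clan == cn, logical(1))]
      usage <- spec$clans[[cn]]$usage
      for (i in seq_len(spec$n_per_class)) {
        wn <- if (length(members) == 1L) members else sample(members, 1L)
        tn <- sample(names(usage), 1L, prob = usage)
        codas[[length(codas) + 1L]] <- make_one(tn, wn)
      }
    }
  } else {
    for (wn in whale_names) {
      usage <- spec$clans[[spec$whales[[wn]]$clan]]$usage
      for (i in seq_len(spec$n_per_class)) {
        tn <- sample(names(usage), 1L, prob = usage)
        codas[[length(codas) + 1L]] <- make_one(tn, wn)
      }
    }
  }
  coda_dataset(codas, provenance = "synthetic")
}

#' Render synthetic click audio
#'
#' Each click is a ~2 ms exponentially decaying 10 kHz transient (inside the
#' detector's 2--20 kHz band) scaled to peak 1, summed into white Gaussian
#' noise whose standard deviation is set by `snr_db` (peak click amplitude
#' over noise RMS, in dB). The signal lasts until 0.5 s after the last
#' click.
#'
#' @param click_times Sorted, non-negative click times in seconds; clicks
#'   closer than 1 ms would overlap and raise an error.
#' @param rate Sampling rate in Hz (>= 44100).
#' @param snr_db Peak-signal-to-noise-RMS ratio in dB.
#' @param seed Integer seed for the noise.
#' @return An [audio_signal()].
#' @export
generate_click_audio <- function(click_times, rate = 48000, snr_db = 30,
                                 seed = 1L) {
  stopifnot(rate >= 44100)
  click_times <- as.numeric(click_times)
  if (length(click_times)) {
    stopifnot(all(click_times >= 0), !is.unsorted(click_times))
    if (length(click_times) > 1L && any(diff(click_times) < 1e-3)) {
      stop("click times closer than 1 ms would overlap")
    }
  }
  dur <- if (length(click_times)) max(click_times) + 0.5 else 0.5
  n <- round(dur * rate)
  set.seed(seed)
  noise_sd <- 10^(-snr_db / 20)
  x <- stats::rnorm(n, sd = noise_sd)
  t_click <- seq(0, 0.002, by = 1 / rate)
  pulse <- exp(-t_click / 3e-4) * sin(2 * pi * 10000 * t_click)
  pulse <- pulse / max(abs(pulse))
  for (ct in click_times) {
    i0 <- round(ct * rate) + 1L
    idx <- i0:min(i0 + length(pulse) - 1L, n)
    x[idx] <- x[idx] + pulse[seq_along(idx)]
  }
  audio_signal(x, rate, origin = "synthetic")
}
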