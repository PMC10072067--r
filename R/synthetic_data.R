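#' Bimodal circadian activity template
#'
#' Mean beam-break counts per 5-min bin over one 24-h cycle, with the
#' classic crepuscular structure: Gaussian bumps centred at ZT0 (morning
#' peak) and ZT12 (evening peak) over a baseline that drops at night,
#' leaving a midday siesta trough between the peaks. Baselines are kept
#' well above zero so an awake bin essentially never records zero counts
#' and scored sleep reflects the programmed sleep state, not shot noise.
#'
#' @param day_level Baseline mean counts/bin during the photophase.
#' @param night_fraction Night baseline as a fraction of `day_level`.
#' @param peak_height Extra mean counts/bin at the peak centres.
#' @param peak_sd_minutes Width (SD) of the peaks in minutes.
#' @param schedule A [light_schedule()] giving bin width and photoperiod.
#' @return Numeric vector of length `period / bin` (288 for 5-min bins).
#' @export
activity_template_bimodal <- function(day_level = 18, night_fraction = 0.35,
                                      peak_height = 30, peak_sd_minutes = 60,
                                      schedule = light_schedule("08:00")) {
  per <- schedule$period_minutes
  zt <- seq(0, per - schedule$bin_minutes, by = schedule$bin_minutes)
  base <- ifelse(zt_is_light(zt, schedule), day_level,
                 day_level * night_fraction)
  circ_dist <- function(a, b) pmin(abs(a - b), per - abs(a - b))
  bump <- function(centre) exp(-circ_dist(zt, centre)^2 / (2 * peak_sd_minutes^2))
  base + peak_height * (bump(0) + bump(schedule$photoperiod_minutes))
}

#' Per-bin sleep/wake transition probabilities
#'
#' Two-state Markov chain rates for the sleep process, piecewise constant
#' over the photophase and scotophase: `p_sleep` is the wake-to-sleep
#' probability per bin, `p_wake` the sleep-to-wake probability. Defaults
#' give a stationary sleep fraction of about 0.30 by day and 0.74 by
#' night, in the range typical of male flies (a pronounced siesta plus
#' consolidated night sleep).
#'
#' @param p_sleep_day,p_wake_day,p_sleep_night,p_wake_night Per-bin
#'   transition probabilities in `[0, 1]`.
#' @param schedule A [light_schedule()].
#' @return List of two vectors (`p_sleep`, `p_wake`), one value per ZT
#'   bin.
#' @export
sleep_chain <- function(p_sleep_day = 0.15, p_wake_day = 0.35,
                        p_sleep_night = 0.35, p_wake_night = 0.12,
                        schedule = light_schedule("08:00")) {
  probs <- c(p_sleep_day, p_wake_day, p_sleep_night, p_wake_night)
  if (any(probs < 0 | probs > 1)) {
    stop("Transition probabilities must lie in [0, 1].", call. = FALSE)
  }
  zt <- seq(0, schedule$period_minutes - schedule$bin_minutes,
            by = schedule$bin_minutes)
  light <- zt_is_light(zt, schedule)
  list(
    p_sleep = ifelse(light, p_sleep_day, p_sleep_night),
    p_wake = ifelse(light, p_wake_day, p_wake_night)
  )
}

#' Weibull lifespan parameters from a median
#'
#' Fly mortality shows an increasing (Gompertz-like) hazard: survival
#' curves are sigmoid, not exponential. A Weibull with shape around 3-5
#' captures this; given a target median lifespan the scale follows from
#' `median = scale * log(2)^(1/shape)`. This is the generator's default
#' lifespan model; a constant-hazard exponential is available for null
#' calibrations.
#'
#' @param median Target median lifespan in days.
#' @param shape Weibull shape (default 4).
#' @return A lifespan spec for [sim_genotype_config()].
#' @export
lifespan_weibull <- function(median, shape = 4) {
  stopifnot(median > 0, shape > 0)
  list(dist = "weibull", shape = shape,
       scale = median / log(2)^(1 / shape))
}

#' Configuration for one simulated genotype
#'
#' Bundles everything the simulator needs for a genotype: the activity
#' template, the sleep chain, the lifespan distribution (exponential by
#' median, or Weibull), a multiplicative daily activity decline with age,
#' and an optional rate of spurious beam breaks during sleep
#' (default 0, so scored sleep is exactly recoverable from programmed
#' truth).
#'
#' @param label Genotype label.
#' @param n_flies Number of flies.
#' @param template Activity template from [activity_template_bimodal()].
#' @param chain Sleep chain from [sleep_chain()].
#' @param lifespan List: either `list(dist = "weibull", shape =, scale =)`
#'   (see [lifespan_weibull()]; the default, median 24.5 days) or
#'   `list(dist = "exponential", median = days)`.
#' @param age_decline Daily multiplicative activity decay (default 0.99).
#' @param noise_rate Poisson mean of false beam breaks per sleeping bin
#'   (default 0).
#' @param schedule A [light_schedule()].
#' @return An object of class `sim_genotype_config`.
#' @export
sim_genotype_config <- function(label, n_flies,
                                template = activity_template_bimodal(schedule = schedule),
                                chain = sleep_chain(schedule = schedule),
                                lifespan = lifespan_weibull(24.5),
                                age_decline = 0.99, noise_rate = 0,
                                schedule = light_schedule("08:00")) {
  bins_per_cycle <- schedule$period_minutes %/% schedule$bin_minutes
  stopifnot(
    length(template) == bins_per_cycle, all(template >= 0),
    length(chain$p_sleep) == bins_per_cycle,
    length(chain$p_wake) == bins_per_cycle,
    all(chain$p_sleep >= 0 & chain$p_sleep <= 1),
    all(chain$p_wake >= 0 & chain$p_wake <= 1),
    n_flies >= 1, age_decline > 0, age_decline <= 1, noise_rate >= 0
  )
  if (!lifespan$dist %in% c("exponential", "weibull")) {
    stop("lifespan$dist must be 'exponential' or 'weibull'.", call. = FALSE)
  }
  if (lifespan$dist == "exponential" && lifespan$median <= 0) {
    stop("Exponential lifespan median must be positive.", call. = FALSE)
  }
  if (lifespan$dist == "weibull" &&
      (lifespan$shape <= 0 || lifespan$scale <= 0)) {
    stop("Weibull lifespan parameters must be positive.", call. = FALSE)
  }
  structure(
    list(label = label, n_flies = as.integer(n_flies), template = template,
         chain = chain, lifespan = lifespan, age_decline = age_decline,
         noise_rate = noise_rate, schedule = schedule),
    class = "sim_genotype_config"
  )
}

#' Programmed (expected) sleep fraction of a genotype
#'
#' The exact time-averaged marginal sleep probability of the configured
#' two-state chain over one cycle, obtained by iterating the one-step
#' marginal recursion `p <- p (1 - p_wake) + (1 - p) p_sleep` around the
#' cycle until it converges to its periodic fixed point. This is the
#' quantity a consistent sleep scorer should recover from long
#' simulations; it is computed from the chain alone, independently of any
#' simulation path.
#'
#' @param cfg A [sim_genotype_config()].
#' @param tol Convergence tolerance on the cycle-start marginal.
#' @return The mean sleep probability over one cycle (scalar in
#'   `[0, 1]`).
#' @export
programmed_sleep_fraction <- function(cfg, tol = 1e-12) {
  ps <- cfg$chain$p_sleep
  pw <- cfg$chain$p_wake
  nb <- length(ps)
  p <- 0.5
  for (iter in 1:1000) {
    p0 <- p
    marg <- numeric(nb)
    for (t in seq_len(nb)) {
      p <- p * (1 - pw[t]) + (1 - p) * ps[t]
      marg[t] <- p
    }
    if (abs(p - p0) < tol) break
  }
  mean(marg)
}

# periodic marginal per ZT bin (used to initialise simulated chains)
chain_marginal <- function(cfg) {
  ps <- cfg$chain$p_sleep
  pw <- cfg$chain$p_wake
  nb <- length(ps)
  p <- 0.5
  marg <- numeric(nb)
  for (iter in 1:1000) {
    p0 <- p
    for (t in seq_len(nb)) {
      p <- p * (1 - pw[t]) + (1 - p) * ps[t]
      marg[t] <- p
    }
    if (abs(p - p0) < 1e-12) break
  }
  marg
}

#' Simulate one fly
#'
#' Sleep state follows the configured two-state Markov chain; awake bins
#' draw Poisson counts with mean `template[zt] * age_decline^(day - 1)`;
#' sleeping bins emit `noise_rate` false breaks (default none); a death
#' time is drawn from the lifespan distribution and every bin from the
#' death bin onward is silent. Fully reproducible given `fly_seed`.
#'
#' @param cfg A [sim_genotype_config()].
#' @param fly_seed Integer seed for this fly's RNG stream.
#' @param n_days Length of the recording in days (default 30).
#' @param fly_id,monitor,channel Identifiers for the recording.
#' @return List with `recording` (an [activity_recording()]) and `truth`
#'   (`death_day`, `death_bin` — `NA` if the fly outlives the recording —
#'   and the programmed per-bin `asleep` state, `NA` after death).
#' @export
simulate_fly <- function(cfg, fly_seed, n_days = 30, fly_id = "sim#01",
                         monitor = "sim", channel = 1L) {
  stopifnot(inherits(cfg, "sim_genotype_config"))
  sch <- cfg$schedule
  bpd <- sch$period_minutes %/% sch$bin_minutes
  n <- as.integer(n_days * bpd)
  zt_idx <- (seq_len(n) - 1L) %% bpd + 1L
  day <- (seq_len(n) - 1L) %/% bpd + 1L

  set.seed(as.integer(fly_seed))
  death_day <- switch(cfg$lifespan$dist,
    exponential = stats::rexp(1, rate = log(2) / cfg$lifespan$median),
    weibull = stats::rweibull(1, shape = cfg$lifespan$shape,
                              scale = cfg$lifespan$scale)
  )
  death_bin <- floor(death_day * 1440 / sch$bin_minutes) + 1
  in_record <- death_bin <= n
  alive <- if (in_record) seq_len(n) < death_bin else rep(TRUE, n)

  u <- stats::runif(n)
  ps <- cfg$chain$p_sleep
  pw <- cfg$chain$p_wake
  asleep <- logical(n)
  asleep[1] <- u[1] < chain_marginal(cfg)[zt_idx[1]]
  for (t in 2:n) {
    asleep[t] <- if (asleep[t - 1L]) u[t] >= pw[zt_idx[t]] else u[t] < ps[zt_idx[t]]
  }

  counts <- integer(n)
  idx_active <- which(alive & !asleep)
  lambda <- cfg$template[zt_idx[idx_active]] *
    cfg$age_decline^(day[idx_active] - 1L)
  counts[idx_active] <- stats::rpois(length(idx_active), lambda)
  if (cfg$noise_rate > 0) {
    idx_noise <- which(alive & asleep)
    counts[idx_noise] <- stats::rpois(length(idx_noise), cfg$noise_rate)
  }
  stopifnot(all(counts[!alive] == 0L))
  truth_asleep <- asleep
  truth_asleep[!alive] <- NA

  rec <- activity_recording(
    fly_id = fly_id, counts = counts, schedule = sch,
    start_time = as.POSIXct(paste("2024-01-01", sch$lights_on), tz = "UTC"),
    genotype = cfg$label, monitor = monitor, channel = channel
  )
  list(
    recording = rec,
    truth = list(
      fly_id = fly_id,
      death_day = if (in_record) death_day else NA_real_,
      death_bin = if (in_record) as.integer(death_bin) else NA_integer_,
      asleep = truth_asleep
    )
  )
}

#' Simulate a cohort of one genotype
#'
#' Each fly gets its own RNG stream derived from
#' `(cohort_seed, fly_index)`, so enlarging a cohort never reshuffles
#' already-simulated flies.
#'
#' @param cfg A [sim_genotype_config()].
#' @param cohort_seed Integer cohort seed.
#' @param n_days Recording length in days (default 30).
#' @param monitor Monitor label used in fly ids.
#' @param first_channel Channel of the first fly (default 1).
#' @return List with `recordings` (list of [activity_recording()]) and
#'   `truth` (data frame: `fly_id`, `genotype`, `death_day`, `death_bin`,
#'   plus a `programmed_sleep_fraction` attribute and per-fly `asleep`
#'   vectors in the `asleep` list attribute).
#' @export
simulate_cohort <- function(cfg, cohort_seed, n_days = 30, monitor = "M1",
                            first_channel = 1L) {
  stopifnot(inherits(cfg, "sim_genotype_config"))
  flies <- lapply(seq_len(cfg$n_flies), function(i) {
    ch <- first_channel + i - 1L
    simulate_fly(
      cfg, fly_seed = derive_fly_seed(cohort_seed, i),
      n_days = n_days,
      fly_id = sprintf("%s#%02d", monitor, ch),
      monitor = monitor, channel = ch
    )
  })
  truth <- data.frame(
    fly_id = vapply(flies, function(f) f$truth$fly_id, character(1)),
    genotype = cfg$label,
    death_day = vapply(flies, function(f) f$truth$death_day, numeric(1)),
    death_bin = vapply(flies, function(f) f$truth$death_bin, integer(1)),
    stringsAsFactors = FALSE
  )
  attr(truth, "asleep") <- lapply(flies, function(f) f$truth$asleep)
  attr(truth, "programmed_sleep_fraction") <- programmed_sleep_fraction(cfg)
  list(recordings = lapply(flies, `[[`, "recording"), truth = truth)
}

derive_fly_seed <- function(cohort_seed, fly_index) {
  as.integer((as.numeric(cohort_seed) * 48271 + fly_index * 9973) %% 2147483647)
}

#' Write recordings as a TriKinetics monitor file
#'
#' Emits the 42-column Monitor dialect [parse_monitor_file()] reads:
#' reading index, date, time, status code 1, six zero metadata columns,
#' then 32 channel-count columns (channels without a recording are
#' written as zeros). All recordings must share start time, bin width and
#' length; at most 32 recordings fit one monitor.
#'
#' @param recordings List of [activity_recording()] objects with channel
#'   numbers set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dam_file <- function(recordings, path) {
  if (length(recordings) > 32L) {
    stop("A monitor holds at most 32 channels.", call. = FALSE)
  }
  stopifnot(length(recordings) >= 1L)
  n <- n_bins(recordings[[1]])
  bin <- recordings[[1]]$schedule$bin_minutes
  start <- recordings[[1]]$start_time
  if (is.null(start)) {
    stop("Recordings need a start_time to be written as a monitor file.",
         call. = FALSE)
  }
  for (rec in recordings) {
    if (n_bins(rec) != n || rec$schedule$bin_minutes != bin) {
      stop("All recordings must share length and bin width.", call. = FALSE)
    }
  }
  ts <- start + (seq_len(n) - 1L) * bin * 60
  counts <- matrix(0L, nrow = n, ncol = 32L)
  for (rec in recordings) {
    ch <- rec$channel
    if (is.na(ch) || ch < 1L || ch > 32L) {
      stop("Recording ", rec$fly_id, " has no valid channel.", call. = FALSE)
    }
    counts[, ch] <- rec$counts
  }
  status <- ifelse(recordings[[1]]$masked, 51L, 1L)
  meta <- cbind(
    seq_len(n),
    format(ts, "%d %b %y"),
    format(ts, "%H:%M:%S"),
    status,
    matrix(0L, nrow = n, ncol = 6L)
  )
  lines <- apply(cbind(meta, counts), 1, paste, collapse = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Simulate lifespans only
#'
#' Draws lifespans from a genotype's configured distribution and censors
#' at the horizon, bypassing the behavioural layer — the fast path for
#' survival-statistics calibration at many replicates.
#'
#' @param cfg A [sim_genotype_config()] (only `lifespan` and `label`
#'   used).
#' @param n Number of flies.
#' @param horizon_days Right-censoring horizon (default 30).
#' @return A vitals-shaped data frame (`fly_id`, `genotype`, `dead`,
#'   `lifespan_days`, `censor_day`).
#' @export
simulate_lifespans <- function(cfg, n = cfg$n_flies, horizon_days = 30) {
  t <- switch(cfg$lifespan$dist,
    exponential = stats::rexp(n, rate = log(2) / cfg$lifespan$median),
    weibull = stats::rweibull(n, shape = cfg$lifespan$shape,
                              scale = cfg$lifespan$scale)
  )
  dead <- t <= horizon_days
  data.frame(
    fly_id = sprintf("%s_%03d", cfg$label, seq_len(n)),
    genotype = cfg$label,
    dead = dead,
    death_bin = NA_integer_,
    lifespan_days = pmin(t, horizon_days),
    censor_day = horizon_days,
    stringsAsFactors = FALSE
  )
}

#' Simulate a negative-binomial DE result table
#'
#' Generates per-gene counts for two conditions (negative binomial with a
#' common dispersion, lognormal baseline means), computes log2
#' fold-changes from the condition means and per-gene p-values from a
#' Wald test on the log ratio of means — the generator knows its own
#' dispersion, so the delta-method variance `(1/mu + phi) / n_rep` per
#' condition is exact fixture machinery, not a DE method — with
#' Benjamini-Hochberg adjustment, and returns the result table together
#' with the programmed true DE sets.
#'
#' @param n_genes Number of genes.
#' @param de_fraction Fraction of genes given a true fold-change.
#' @param lfc_range True absolute log2 fold-changes are drawn uniformly
#'   from this range (sign random).
#' @param n_rep Replicates per condition (default 3).
#' @param dispersion NB dispersion (default 0.05).
#' @param base_meanlog,base_sdlog Lognormal parameters of baseline means.
#' @param seed Integer seed.
#' @return A data frame (`gene_id`, `log2fc`, `padj`, `total_reads`) with
#'   attributes `true_up` and `true_down`.
#' @export
simulate_de_table <- function(n_genes = 2000, de_fraction = 0.05,
                              lfc_range = c(1.5, 3), n_rep = 3,
                              dispersion = 0.05, base_meanlog = log(100),
                              base_sdlog = 1, seed = 1) {
  set.seed(as.integer(seed))
  mu0 <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  n_de <- round(de_fraction * n_genes)
  de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
  lfc_true <- numeric(n_genes)
  if (n_de > 0) {
    lfc_true[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::runif(n_de, lfc_range[1], lfc_range[2])
  }
  size <- 1 / dispersion
  ctrl <- matrix(stats::rnbinom(n_genes * n_rep, mu = mu0, size = size),
                 nrow = n_genes)
  cond <- matrix(stats::rnbinom(n_genes * n_rep, mu = mu0 * 2^lfc_true,
                                size = size), nrow = n_genes)
  m_c <- rowMeans(ctrl) + 0.5
  m_t <- rowMeans(cond) + 0.5
  log2fc <- log2(m_t / m_c)
  # delta-method variance of log(mean) under NB(mu, phi): (1/mu + phi)/n
  se <- sqrt((1 / m_c + dispersion) / n_rep + (1 / m_t + dispersion) / n_rep)
  z <- log(m_t / m_c) / se
  p <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(p, method = "BH")
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  out <- data.frame(
    gene_id = gene_id,
    log2fc = log2fc,
    padj = padj,
    total_reads = as.integer(rowSums(ctrl) + rowSums(cond)),
    stringsAsFactors = FALSE
  )
  attr(out, "true_up") <- gene_id[lfc_true > 0]
  attr(out, "true_down") <- gene_id[lfc_true < 0]
  out
}

#' Engineer a pair of DE tables with programmed overlaps
#'
#' Deterministic fixture builder: two comparisons sharing a programmed
#' number of up- and down-regulated genes, plus per-comparison unique
#' DEGs, null genes, and genes below the 10-read prefilter. Effect sizes
#' and adjusted p-values are set far past the thresholds so the
#' programmed sets are recovered exactly.
#'
#' @param shared_up,shared_down Genes DE in both comparisons.
#' @param unique_up_a,unique_down_a,unique_up_b,unique_down_b
#'   Per-comparison unique DEGs.
#' @param n_null Non-DE genes present in both tables.
#' @param n_low Genes with `total_reads < 10` (to exercise the
#'   prefilter).
#' @return List of two DE data frames, `a` and `b`.
#' @export
make_deg_fixture <- function(shared_up = 5, shared_down = 8,
                             unique_up_a = 7, unique_down_a = 9,
                             unique_up_b = 14, unique_down_b = 10,
                             n_null = 50, n_low = 6) {
  ids <- function(prefix, n) {
    if (n > 0) sprintf("%s%03d", prefix, seq_len(n)) else character(0)
  }
  su <- ids("shup", shared_up); sd_ <- ids("shdn", shared_down)
  one_table <- function(up_unique, down_unique) {
    up <- c(su, up_unique); down <- c(sd_, down_unique)
    null_ids <- ids("null", n_null); low_ids <- ids("low", n_low)
    data.frame(
      gene_id = c(up, down, null_ids, low_ids),
      log2fc = c(rep(2.5, length(up)), rep(-2.5, length(down)),
                 rep(0.1, n_null), rep(3, n_low)),
      padj = c(rep(1e-6, length(up) + length(down)), rep(0.9, n_null),
               rep(1e-6, n_low)),
      total_reads = c(rep(500L, length(up) + length(down) + n_null),
                      rep(5L, n_low)),
      stringsAsFactors = FALSE
    )
  }
  list(
    a = one_table(ids("aup", unique_up_a), ids("adn", unique_down_a)),
    b = one_table(ids("bup", unique_up_b), ids("bdn", unique_down_b))
  )
}

#' Simulate per-unit count data (haemocytes, glia, ...)
#'
#' Lognormal per-unit values with the given group means and coefficient
#' of variation — the overdispersed, strictly positive structure of
#' haemocytometer counts. Default means follow the scale of larval
#' haemocyte concentrations (about 1.3-4.0 x 10^5 cells/mL).
#'
#' @param group_means Named vector of true group means.
#' @param cv Coefficient of variation (default 0.3).
#' @param n_per_group Units per group (recycled to the number of groups).
#' @param unit_kind `"larva"`, `"brain"` or `"vial"`.
#' @param seed Integer seed.
#' @return A data frame (`unit_id`, `genotype`, `value`, `unit_kind`).
#' @export
simulate_count_table <- function(group_means = c(control = 1.29e5,
                                                 wt = 1.94e5,
                                                 R1261C = 3.97e5),
                                 cv = 0.3, n_per_group = 30,
                                 unit_kind = "larva", seed = 1) {
  stopifnot(all(group_means > 0), cv >= 0)
  set.seed(as.integer(seed))
  n_per_group <- rep_len(n_per_group, length(group_means))
  sdlog <- sqrt(log(1 + cv^2))
  rows <- mapply(function(g, m, n) {
    meanlog <- log(m) - sdlog^2 / 2
    data.frame(
      unit_id = sprintf("%s_%03d", g, seq_len(n)),
      genotype = g,
      value = if (cv == 0) rep(m, n) else stats::rlnorm(n, meanlog, sdlog),
      unit_kind = unit_kind,
      stringsAsFactors = FALSE
    )
  }, names(group_means), group_means, n_per_group, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate replicate eclosion counts
#'
#' Binomial eclosion per replicate vial at the given true rates,
#' mirroring the three-vials-of-twenty-larvae design of developmental
#' survival assays.
#'
#' @param rates Named vector of true eclosion probabilities per genotype.
#' @param n_vials Replicate vials per genotype (default 3).
#' @param n_larvae Larvae per vial (default 20).
#' @param seed Integer seed.
#' @return A data frame (`genotype`, `replicate`, `n_input_larvae`,
#'   `n_eclosed`).
#' @export
simulate_eclosion_table <- function(rates, n_vials = 3, n_larvae = 20,
                                    seed = 1) {
  stopifnot(all(rates >= 0 & rates <= 1))
  set.seed(as.integer(seed))
  rows <- lapply(names(rates), function(g) {
    data.frame(
      genotype = g,
      replicate = seq_len(n_vials),
      n_input_larvae = n_larvae,
      n_eclosed = stats::rbinom(n_vials, n_larvae, rates[[g]]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
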