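#' Configuration for the synthetic phyllosphere experiment
#'
#' Bundles every tunable of the synthetic-data generator. The defaults emulate
#' a density-series spray-inoculation experiment on axenically grown plants:
#' a mock control plus four inoculation densities spanning 10^5 to 10^8
#' CFU mL^-1, three biological replicates each, negative-binomial counts with
#' a dose-dependent planted response, a 9-state chromatin segmentation, Cq
#' values generated through the primer-efficiency model, and log-normally
#' noisy colony counts tracking the inoculum.
#'
#' @param seed Integer master seed. Every generator derives its own stream
#'   from it, so the same configuration always produces byte-identical files.
#' @param n_genes Number of genes to place on the synthetic genome.
#' @param n_states Number of chromatin states (default 9).
#' @param state_props Genome-wide coverage fraction per state; must sum to 1.
#' @param genome_length Genome length in bp.
#' @param seg_length_mean Mean chromatin segment length in bp (exponential
#'   lengths), short relative to genes so single genes span several states.
#' @param gene_length_mean,gene_length_sd Gene length distribution in bp.
#' @param treatments Data frame with columns `name` and `density`
#'   (inoculum CFU mL^-1; the mock control has density 0).
#' @param n_reps Biological replicates per treatment.
#' @param lib_size_cv Coefficient of variation of the log-normal library
#'   size factors (mean 1).
#' @param dispersion Negative-binomial dispersion phi (>= 0; 0 gives Poisson).
#' @param frac_de Fraction of genes that respond to inoculation.
#' @param beta_scale Magnitude of the planted log2 fold change at the
#'   reference (highest) density; every responsive gene carries |beta| equal
#'   to this value so the planted effect size is exactly known.
#' @param frac_down Fraction of responsive genes that are repressed
#'   (negative beta); default 1/3, echoing the roughly 2:1 up:down split
#'   seen in plant responses to leaf colonizers.
#' @param dose_curve `"log-linear"` (default) or `"hill"`; shape of the
#'   response scaling f(density) with f(reference density) = 1 and f(0) = 0.
#' @param d_min Density at or below which the log-linear response is zero.
#' @param d_ref Reference density (default: maximum treatment density).
#' @param hill_coef Hill coefficient when `dose_curve = "hill"`.
#' @param state_de_bias Per-state relative odds that a gene in that state is
#'   responsive; all-equal means no planted chromatin enrichment.
#' @param baseline_mean,baseline_sdlog Log-normal baseline expected counts.
#' @param cq_noise_sd Gaussian noise on simulated Cq values, in cycles.
#' @param cq_timepoints Timepoints (h) at which qPCR samples are simulated.
#' @param cfu_noise_sd Log10-scale noise on simulated bacterial densities.
#' @param cfu_intercept,cfu_slope Colonization line:
#'   log10 CFU g^-1 = intercept + slope * log10(inoculum).
#' @param n_cfu_reps Plants plated per treatment.
#' @param plant_weight,plant_weight_sd Plant fresh weight in g (Gaussian,
#'   truncated at 0.01 g; sd 0 keeps weights fixed).
#' @param plated_fraction Fraction of the resuspension plated.
#' @param resuspension_volume Resuspension volume in mL (bookkeeping only;
#'   the plated fraction already encodes it).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_states = 9L,
                       state_props = rep(1 / n_states, n_states),
                       genome_length = 2e7,
                       seg_length_mean = 800,
                       gene_length_mean = 2000,
                       gene_length_sd = 600,
                       treatments = default_treatments(),
                       n_reps = 3L,
                       lib_size_cv = 0.2,
                       dispersion = 0.05,
                       frac_de = 0.1,
                       beta_scale = 3,
                       frac_down = 1 / 3,
                       dose_curve = c("log-linear", "hill"),
                       d_min = 1e3,
                       d_ref = NULL,
                       hill_coef = 2,
                       state_de_bias = rep(1, n_states),
                       baseline_mean = 300,
                       baseline_sdlog = 1.2,
                       cq_noise_sd = 0.2,
                       cq_timepoints = 96,
                       cfu_noise_sd = 0.25,
                       cfu_intercept = 0,
                       cfu_slope = 1,
                       n_cfu_reps = 4L,
                       plant_weight = 0.1,
                       plant_weight_sd = 0,
                       plated_fraction = 0.1,
                       resuspension_volume = 1) {
  dose_curve <- match.arg(dose_curve)
  treatments <- as_tibble(treatments)
  assert_cols(treatments, c("name", "density"), "treatments")
  assert_that(abs(sum(state_props) - 1) <= 1e-9, "state_props must sum to 1")
  assert_that(length(state_props) == n_states,
              "state_props must have one entry per state")
  assert_that(length(state_de_bias) == n_states,
              "state_de_bias must have one entry per state")
  assert_that(all(state_props > 0), "state_props must be positive")
  assert_that(n_genes > 0 && n_states > 0 && n_reps > 0, "counts must be > 0")
  assert_that(dispersion >= 0, "dispersion must be >= 0")
  assert_that(frac_de >= 0 && frac_de <= 1, "frac_de must be in [0, 1]")
  assert_that(all(treatments$density >= 0), "densities must be >= 0")
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_states = as.integer(n_states), state_props = state_props,
    genome_length = genome_length, seg_length_mean = seg_length_mean,
    gene_length_mean = gene_length_mean, gene_length_sd = gene_length_sd,
    treatments = treatments, n_reps = as.integer(n_reps),
    lib_size_cv = lib_size_cv, dispersion = dispersion,
    frac_de = frac_de, beta_scale = beta_scale, frac_down = frac_down,
    dose_curve = dose_curve, d_min = d_min,
    d_ref = d_ref %||% max(treatments$density), hill_coef = hill_coef,
    state_de_bias = state_de_bias,
    baseline_mean = baseline_mean, baseline_sdlog = baseline_sdlog,
    cq_noise_sd = cq_noise_sd, cq_timepoints = cq_timepoints,
    cfu_noise_sd = cfu_noise_sd, cfu_intercept = cfu_intercept,
    cfu_slope = cfu_slope, n_cfu_reps = as.integer(n_cfu_reps),
    plant_weight = plant_weight, plant_weight_sd = plant_weight_sd,
    plated_fraction = plated_fraction,
    resuspension_volume = resuspension_volume
  )
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_treatments <- function() {
  tibble(name = c("mock", "d1e5", "d1e6", "d1e7", "d1e8"),
         density = c(0, 1e5, 1e6, 1e7, 1e8))
}

#' Dose-response scaling of the planted effect
#'
#' Maps an inoculation density to the fraction of the full planted log2
#' fold change expressed at that density. Monotone nondecreasing in
#' log10(density), 0 for mock (density 0) and 1 at the reference density.
#'
#' @param density Inoculum densities (CFU mL^-1).
#' @param cfg A [sim_config()].
#' @return Numeric vector of scalings in [0, 1] (log-linear curve can exceed
#'   1 above the reference density).
#' @export
dose_scaling <- function(density, cfg) {
  f <- numeric(length(density))
  pos <- density > 0
  ld <- log10(density[pos])
  if (cfg$dose_curve == "log-linear") {
    f[pos] <- pmax(0, (ld - log10(cfg$d_min)) /
                     (log10(cfg$d_ref) - log10(cfg$d_min)))
  } else {
    half <- (log10(cfg$d_min) + log10(cfg$d_ref)) / 2
    raw <- ld^cfg$hill_coef / (half^cfg$hill_coef + ld^cfg$hill_coef)
    ref <- log10(cfg$d_ref)^cfg$hill_coef /
      (half^cfg$hill_coef + log10(cfg$d_ref)^cfg$hill_coef)
    f[pos] <- raw / ref
  }
  f
}

#' Simulate a chromatin-state genome segmentation
#'
#' Tiles `[0, genome_length)` with contiguous, non-overlapping segments whose
#' lengths are exponential (minimum 150 bp) and whose state labels are drawn
#' by a coverage-deficit rule: each new segment picks a state with probability
#' proportional to how far that state currently lags its target genome-wide
#' coverage. Realized coverage therefore tracks `state_props` to well within
#' 2% for genomes of 1 Mb and up, while the interleaving of states along the
#' genome remains random.
#'
#' @param cfg A [sim_config()].
#' @return Tibble (chrom, start, end, state) in 0-based half-open
#'   coordinates; states are labelled "1".."n_states".
#' @export
simulate_segmentation <- function(cfg) {
  withr::with_seed(stage_seed(cfg$seed, "segmentation"), {
    min_len <- 150
    assert_that(cfg$genome_length >= cfg$n_states * min_len,
                sprintf("genome_length too small to realize state %d", cfg$n_states))
    n_guess <- ceiling(cfg$genome_length / cfg$seg_length_mean * 1.5) + cfg$n_states
    lens <- pmax(min_len, round(stats::rexp(n_guess, 1 / cfg$seg_length_mean)))
    while (sum(lens) < cfg$genome_length) {
      lens <- c(lens, pmax(min_len, round(stats::rexp(n_guess, 1 / cfg$seg_length_mean))))
    }
    n_seg <- which(cumsum(lens) >= cfg$genome_length)[1]
    lens <- lens[seq_len(n_seg)]
    lens[n_seg] <- cfg$genome_length - sum(lens[-n_seg])
    if (lens[n_seg] < 1) {
      lens <- lens[-n_seg]
      n_seg <- n_seg - 1
    }
    states <- integer(n_seg)
    covered <- numeric(cfg$n_states)
    total <- 0
    for (i in seq_len(n_seg)) {
      deficit <- cfg$state_props * (total + lens[i]) - covered
      w <- pmax(deficit, 0)
      if (sum(w) == 0) w <- cfg$state_props
      states[i] <- sample.int(cfg$n_states, 1, prob = w)
      covered[states[i]] <- covered[states[i]] + lens[i]
      total <- total + lens[i]
    }
    missing <- which(covered == 0)
    if (length(missing) > 0) {
      stop(sprintf("genome_length too small to realize state %d", missing[1]),
           call. = FALSE)
    }
    ends <- cumsum(lens)
    tibble(chrom = "chr1", start = c(0, ends[-n_seg]), end = ends,
           state = as.character(states))
  })
}

#' Simulate non-overlapping gene coordinates on a segmented genome
#'
#' Places `n_genes` genes uniformly at random without overlap (rejection
#' sampling, capped at 100 attempts per gene) and assigns chromatin states
#' to each gene with the same >= 150 bp overlap rule used by
#' [assign_states()] — the two share one code path.
#'
#' @param cfg A [sim_config()].
#' @param seg Segmentation from [simulate_segmentation()].
#' @param min_overlap Overlap rule threshold in bp (default 150).
#' @return List with `genes` (tibble: gene_id, chrom, start, end, strand,
#'   0-based half-open) and `gene_states` (a [assign_states()] result).
#' @export
simulate_genes <- function(cfg, seg, min_overlap = 150) {
  genes <- withr::with_seed(stage_seed(cfg$seed, "genes"), {
    lens <- pmax(300, round(stats::rnorm(cfg$n_genes, cfg$gene_length_mean,
                                         cfg$gene_length_sd)))
    starts <- numeric(cfg$n_genes)
    ends <- numeric(cfg$n_genes)
    placed_start <- numeric(0)
    placed_end <- numeric(0)
    max_attempts <- 100 * cfg$n_genes
    attempts <- 0
    for (i in seq_len(cfg$n_genes)) {
      repeat {
        attempts <- attempts + 1
        if (attempts > max_attempts) {
          stop(sprintf("could not place %d non-overlapping genes (placed %d)",
                       cfg$n_genes, i - 1L), call. = FALSE)
        }
        s <- floor(stats::runif(1, 0, cfg$genome_length - lens[i]))
        e <- s + lens[i]
        # neighbours in the sorted list of placed intervals
        k <- findInterval(s, placed_start)
        clash <- (k >= 1 && placed_end[k] > s) ||
          (k < length(placed_start) && placed_start[k + 1] < e)
        if (!clash) {
          ins <- k + 1
          placed_start <- append(placed_start, s, after = k)
          placed_end <- append(placed_end, e, after = k)
          starts[i] <- s
          ends[i] <- e
          break
        }
      }
    }
    ord <- order(starts)
    tibble(gene_id = sprintf("g%05d", seq_len(cfg$n_genes)),
           chrom = "chr1",
           start = starts[ord], end = ends[ord],
           strand = rep_len(c("+", "-"), cfg$n_genes))
  })
  gene_states <- assign_states(genes, seg, min_overlap = min_overlap)
  list(genes = genes, gene_states = gene_states)
}

# Pick responsive genes with per-state odds, and signed effect sizes.
choose_de_genes <- function(cfg, genes, gene_states) {
  n_de <- round(cfg$frac_de * cfg$n_genes)
  beta <- stats::setNames(numeric(cfg$n_genes), genes$gene_id)
  if (n_de == 0) {
    return(list(de_genes = character(0), beta = beta))
  }
  # gene weight = product of the odds of its distinct states (1 if none);
  # odds from independent state memberships combine multiplicatively
  w <- gene_states |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(w = prod(cfg$state_de_bias[as.integer(.data$state)]),
                     .groups = "drop")
  weights <- stats::setNames(rep(1, cfg$n_genes), genes$gene_id)
  weights[w$gene_id] <- w$w
  de <- sample(genes$gene_id, n_de, prob = weights)
  n_down <- round(cfg$frac_down * n_de)
  down <- if (n_down > 0) sample(de, n_down) else character(0)
  beta[de] <- cfg$beta_scale
  beta[down] <- -cfg$beta_scale
  list(de_genes = de, beta = beta)
}

#' Simulate an RNA-seq count matrix with a planted dose-dependent response
#'
#' Counts follow y ~ NB(mean = baseline_g * s_j * 2^(beta_g * f(d_j)),
#' dispersion phi), where f is the monotone dose curve of [dose_scaling()]
#' (f = 0 for mock samples, 1 at the reference density), s_j are log-normal
#' library size factors with the configured CV, and responsive genes are
#' drawn with per-state odds `state_de_bias` so chromatin-state enrichment
#' can be planted among them.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_counts` with elements `counts` (wide tibble:
#'   gene_id + one column per sample), `samples` (sample sheet tibble:
#'   sample_id, treatment, density, replicate) and `truth` (list: de_genes,
#'   beta, genes, gene_states, segmentation, baseline, size_factors).
#' @export
simulate_counts <- function(cfg) {
  seg <- simulate_segmentation(cfg)
  ga <- simulate_genes(cfg, seg)
  withr::with_seed(stage_seed(cfg$seed, "counts"), {
    de <- choose_de_genes(cfg, ga$genes, ga$gene_states)
    baseline <- stats::rlnorm(cfg$n_genes, log(cfg$baseline_mean),
                              cfg$baseline_sdlog)
    names(baseline) <- ga$genes$gene_id
    samples <- tidyr::crossing(cfg$treatments,
                               replicate = seq_len(cfg$n_reps)) |>
      dplyr::transmute(
        sample_id = sprintf("%s_r%d", .data$name, .data$replicate),
        treatment = .data$name, density = .data$density,
        replicate = .data$replicate)
    sigma <- sqrt(log(1 + cfg$lib_size_cv^2))
    s <- stats::rlnorm(nrow(samples), -sigma^2 / 2, sigma)
    f <- dose_scaling(samples$density, cfg)
    mu <- outer(baseline, s) * 2^(de$beta %o% f)
    m <- matrix(0, cfg$n_genes, nrow(samples),
                dimnames = list(ga$genes$gene_id, samples$sample_id))
    n <- length(mu)
    if (cfg$dispersion == 0) {
      m[] <- stats::rpois(n, mu)
    } else {
      m[] <- stats::rnbinom(n, size = 1 / cfg$dispersion, mu = mu)
    }
    structure(list(
      counts = matrix_to_counts(m),
      samples = samples,
      truth = list(de_genes = de$de_genes, beta = de$beta,
                   genes = ga$genes, gene_states = ga$gene_states,
                   segmentation = seg, baseline = baseline,
                   size_factors = stats::setNames(s, samples$sample_id))
    ), class = "sim_counts")
  })
}

#' Simulate a qPCR Cq table from planted expression effects
#'
#' Inverts the primer-efficiency model: a transcript present at relative
#' concentration c with primer efficiency E yields Cq = -log(c)/log(E),
#' plus Gaussian cycle noise. Marker genes carry the planted log2 fold
#' change beta_g * f(density); two synthetic reference genes (REF1, REF2)
#' are constitutively expressed (beta = 0).
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list from [simulate_counts()] (used for beta); if
#'   NULL, marker effects are drawn fresh with magnitude `beta_scale`.
#' @param markers Marker gene IDs; default picks up to 3 induced and 1
#'   repressed responsive gene from the truth.
#' @return List with `cq` (tibble: sample_id, treatment, timepoint_h,
#'   replicate, gene_id, cq, efficiency), `reference_genes`,
#'   `mock` label, and `truth_log2fc` (tibble of planted per-sample log2FC).
#' @export
simulate_qpcr <- function(cfg, truth = NULL, markers = NULL) {
  withr::with_seed(stage_seed(cfg$seed, "qpcr"), {
    if (is.null(truth)) {
      beta <- stats::setNames(c(cfg$beta_scale, cfg$beta_scale, -cfg$beta_scale),
                              c("MRK1", "MRK2", "MRK3"))
    } else {
      beta <- truth$beta
    }
    if (is.null(markers)) {
      up <- names(beta)[beta > 0]
      dn <- names(beta)[beta < 0]
      markers <- c(utils::head(up, 3), utils::head(dn, 1))
      assert_that(length(markers) > 0, "no responsive genes to use as markers")
    }
    refs <- c("REF1", "REF2")
    genes <- c(markers, refs)
    beta_all <- stats::setNames(rep(0, length(genes)), genes)
    beta_all[markers] <- beta[markers]
    eff <- stats::setNames(round(stats::runif(length(genes), 1.85, 2), 3), genes)
    cq0 <- stats::setNames(round(stats::runif(length(genes), 18, 24), 2), genes)
    grid <- tidyr::crossing(cfg$treatments,
                            timepoint_h = cfg$cq_timepoints,
                            replicate = seq_len(cfg$n_reps),
                            gene_id = genes)
    f <- dose_scaling(grid$density, cfg)
    log2fc_true <- beta_all[grid$gene_id] * f
    conc0 <- (1 / eff[grid$gene_id])^(cq0[grid$gene_id])
    conc <- conc0 * 2^log2fc_true
    cq <- -log(conc) / log(eff[grid$gene_id]) +
      stats::rnorm(nrow(grid), 0, cfg$cq_noise_sd)
    out <- grid |>
      dplyr::transmute(
        sample_id = sprintf("%s_t%g_r%d", .data$name, .data$timepoint_h,
                            .data$replicate),
        treatment = .data$name, timepoint_h = .data$timepoint_h,
        replicate = .data$replicate, gene_id = .data$gene_id,
        cq = cq, efficiency = eff[.data$gene_id])
    truth_fc <- dplyr::bind_cols(out[, c("sample_id", "treatment",
                                         "timepoint_h", "replicate", "gene_id")],
                                 tibble(log2fc_true = unname(log2fc_true)))
    list(cq = out, reference_genes = refs, mock = "mock",
         truth_log2fc = truth_fc)
  })
}

#' Simulate colony-count (CFU) plating data
#'
#' True densities follow log10 CFU g^-1 = a + b log10(inoculum) + N(0, sd);
#' mock plants carry no bacteria. Colony counts are back-computed through
#' plant weight, plated fraction and an adaptively chosen decimal dilution
#' targeting a countable plate; samples whose expected plate count falls
#' below one colony are recorded as colony_count 0 (below detection), never
#' dropped.
#'
#' @param cfg A [sim_config()].
#' @return List with `cfu` (tibble: sample_id, treatment, timepoint_h,
#'   colony_count, dilution_factor, plated_fraction, resuspension_volume,
#'   plant_weight) and `true_cfu` (named vector, CFU g^-1).
#' @export
simulate_cfu <- function(cfg) {
  withr::with_seed(stage_seed(cfg$seed, "cfu"), {
    grid <- tidyr::crossing(cfg$treatments,
                            replicate = seq_len(cfg$n_cfu_reps))
    inoc <- grid$density
    true_log10 <- ifelse(inoc > 0,
                         cfg$cfu_intercept + cfg$cfu_slope * log10(inoc) +
                           stats::rnorm(nrow(grid), 0, cfg$cfu_noise_sd),
                         -Inf)
    true_cfu <- ifelse(is.finite(true_log10), 10^true_log10, 0)
    weight <- pmax(0.01, stats::rnorm(nrow(grid), cfg$plant_weight,
                                      cfg$plant_weight_sd))
    expected0 <- true_cfu * weight * cfg$plated_fraction
    dilution <- 10^pmax(0, ceiling(log10(pmax(expected0, 1) / 200)))
    colonies <- round(expected0 / dilution)
    out <- grid |>
      dplyr::transmute(
        sample_id = sprintf("%s_c%d", .data$name, .data$replicate),
        treatment = .data$name, timepoint_h = 96,
        colony_count = as.integer(colonies),
        dilution_factor = dilution,
        plated_fraction = cfg$plated_fraction,
        resuspension_volume = cfg$resuspension_volume,
        plant_weight = weight)
    list(cfu = out, true_cfu = stats::setNames(true_cfu, out$sample_id))
  })
}
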