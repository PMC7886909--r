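#' Cohort generator configuration
#'
#' Holds the planted effect sizes of the synthetic trial cohort. Defaults are
#' the effect sizes the study printed: a 3.4-fold responder increase in the
#' DP (CD103+CD39+) fraction of CD8 TIL and in Ki-67+ DP cells, a 6.8-fold
#' peripheral CD4 Ki-67 peak, a 4-6-fold CD8 proliferation peak, a 10-fold
#' plasmablast peak, and a responder fraction of 0.25 (4 of 16 evaluable
#' patients). The modest responder lift on %CD8 of T cells defaults to 2.
#'
#' @param n_patients Number of patients (>= 1).
#' @param responder_fraction Proportion of planted responders in \[0, 1\].
#' @param dp_fold_responder Responder fold on %DP of CD8 and %Ki-67 of DP.
#' @param cd8_fold_responder Modest responder fold on %CD8 of T.
#' @param ki67_cd4_fold Peripheral CD4 Ki-67 peak fold (time course).
#' @param cd8_blood_fold_range Peripheral CD8 proliferation peak fold range;
#'   the midpoint is planted.
#' @param plasmablast_fold Peripheral plasmablast peak fold (time course).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise on each fold-change component, in \[0, 1\].
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   exactly.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 16, responder_fraction = 0.25,
                          dp_fold_responder = 3.4, cd8_fold_responder = 2,
                          ki67_cd4_fold = 6.8, cd8_blood_fold_range = c(4, 6),
                          plasmablast_fold = 10, noise_cv = 0.2, seed = 1) {
  check_proportion(responder_fraction, "responder_fraction")
  check_proportion(noise_cv, "noise_cv")
  folds <- c(dp_fold_responder = dp_fold_responder,
             cd8_fold_responder = cd8_fold_responder,
             ki67_cd4_fold = ki67_cd4_fold,
             plasmablast_fold = plasmablast_fold,
             cd8_blood_fold_range)
  if (any(folds <= 0)) {
    abort("all configured fold changes must be positive",
          class = "tilmonitor_bad_config")
  }
  stopifnot(n_patients >= 1, length(cd8_blood_fold_range) == 2)
  structure(list(
    n_patients = as.integer(n_patients),
    responder_fraction = responder_fraction,
    dp_fold_responder = dp_fold_responder,
    cd8_fold_responder = cd8_fold_responder,
    ki67_cd4_fold = ki67_cd4_fold,
    cd8_blood_fold_range = cd8_blood_fold_range,
    plasmablast_fold = plasmablast_fold,
    noise_cv = noise_cv,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

check_proportion <- function(x, field) {
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", field, "` must be a proportion in [0, 1]"),
          class = "tilmonitor_bad_config")
  }
  invisible(x)
}

#' Repertoire generator configuration
#'
#' The clone-abundance model is a discrete power law over clone ranks
#' (`p_i` proportional to `i^-alpha`), sampled multinomially at the
#' configured sequencing depth — the simplest generator that reproduces the
#' heavy-tailed dominance of top clones seen in sorted DP TIL. DN and SP
#' draw `shared_pool_fraction` of their probability mass from one common
#' clone pool (with identical rank assignment, so their shared mass is
#' correlated), while DP places `dp_private_fraction` of its mass on clones
#' absent from every other compartment.
#'
#' @param n_clones Clones per compartment source distribution (>= 2).
#' @param powerlaw_alpha Abundance exponent (> 1).
#' @param depth Total template count per repertoire (>= n_clones).
#' @param shared_pool_fraction Proportion of DN/SP mass from the common pool.
#' @param dp_private_fraction Proportion of DP mass on private clones.
#' @param nonproductive_fraction Probability a sampled clone is flagged
#'   non-productive (out-of-frame); default 0.05.
#' @param seed Integer seed.
#' @return A validated `repertoire_config` list.
#' @export
repertoire_config <- function(n_clones = 1000, powerlaw_alpha = 2,
                              depth = 1e5, shared_pool_fraction = 0.8,
                              dp_private_fraction = 0.95,
                              nonproductive_fraction = 0.05, seed = 1) {
  check_proportion(shared_pool_fraction, "shared_pool_fraction")
  check_proportion(dp_private_fraction, "dp_private_fraction")
  check_proportion(nonproductive_fraction, "nonproductive_fraction")
  stopifnot(n_clones >= 2, powerlaw_alpha > 1, depth >= n_clones)
  structure(list(
    n_clones = as.integer(n_clones),
    powerlaw_alpha = powerlaw_alpha,
    depth = as.integer(depth),
    shared_pool_fraction = shared_pool_fraction,
    dp_private_fraction = dp_private_fraction,
    nonproductive_fraction = nonproductive_fraction,
    seed = as.integer(seed)
  ), class = "repertoire_config")
}

# one representative codon per amino acid; enough to give clones a plausible
# nucleotide identity whose translation matches cdr3_aa
AA_CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

random_cdr3 <- function(n) {
  # CDR3s start with the conserved cysteine and end with phenylalanine
  lens <- sample(10:16, n, replace = TRUE)
  aa <- vapply(lens, function(L) {
    paste0("C", paste(sample(names(AA_CODON), L - 2, replace = TRUE),
                      collapse = ""), "F")
  }, character(1))
  # synonymous wobble in the first internal codon keeps nt identities unique
  nt <- vapply(aa, function(s) {
    paste(AA_CODON[strsplit(s, "")[[1]]], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  while (anyDuplicated(nt)) {
    dup <- duplicated(nt)
    extra <- random_cdr3(sum(dup))
    aa[dup] <- extra$cdr3_aa
    nt[dup] <- extra$cdr3_nt
  }
  tibble::tibble(cdr3_nt = nt, cdr3_aa = aa)
}

zipf_probs <- function(n, alpha) {
  p <- seq_len(n)^(-alpha)
  p / sum(p)
}

sample_repertoire <- function(pool, probs, depth, nonprod_frac) {
  counts <- as.integer(rmultinom(1, size = depth, prob = probs))
  keep <- counts > 0
  rep <- pool[keep, , drop = FALSE]
  rep$count <- counts[keep]
  rep$productive <- runif(nrow(rep)) >= nonprod_frac
  as_repertoire(rep)
}

#' Generate sorted-subset repertoires with planted sharing structure
#'
#' Produces six repertoires — `blood_pre`, `blood_post`, `drLN`, `DN`, `SP`,
#' `DP` — each a multinomial sample of the configured depth from a power-law
#' clone-abundance distribution. Blood, draining lymph node, DN and SP draw
#' most of their mass from one shared clone pool with a common rank
#' assignment (so DN/SP overlap is high), whereas DP places
#' `dp_private_fraction` of its mass on clones found nowhere else — the
#' planted analogue of a tumor-resident subset with a unique repertoire.
#'
#' @param cfg A [repertoire_config()].
#' @return Named list of repertoire tibbles; counts sum to `cfg$depth` per
#'   repertoire.
#' @export
gen_repertoires <- function(cfg = repertoire_config()) {
  stopifnot(inherits(cfg, "repertoire_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_clones
    shared <- random_cdr3(n)
    privates <- lapply(c(DN = 1, SP = 2, DP = 3), function(i) random_cdr3(n))
    base <- zipf_probs(n, cfg$powerlaw_alpha)

    mix <- function(private_pool, private_mass) {
      pool <- dplyr::bind_rows(shared, private_pool)
      probs <- c(base * (1 - private_mass), base * private_mass)
      list(pool = pool, probs = probs)
    }
    w_priv_dnsp <- 1 - cfg$shared_pool_fraction
    sources <- list(
      blood_pre = list(pool = shared, probs = base),
      blood_post = list(pool = shared, probs = base),
      drLN = list(pool = shared, probs = base),
      DN = mix(privates$DN, w_priv_dnsp),
      SP = mix(privates$SP, w_priv_dnsp),
      DP = mix(privates$DP, cfg$dp_private_fraction)
    )
    lapply(sources, function(s) {
      sample_repertoire(s$pool, s$probs, cfg$depth, cfg$nonproductive_fraction)
    })
  })
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog) # mean-1 multiplier
}

#' Generate a flow cohort with planted responder effects
#'
#' Each patient gets a baseline and a day-of-surgery (DOS) panel of the three
#' activation-index percentages. Planted responders receive multiplicative
#' lifts (`dp_fold_responder` on %DP of CD8 and on %Ki-67 of DP,
#' `cd8_fold_responder` on %CD8 of T); non-responders receive fold 1. Every
#' fold-change component is perturbed by one unbiased lognormal multiplier at
#' `noise_cv`. Ground-truth labels are returned in a sidecar table, never in
#' the panels themselves.
#'
#' @param cfg A [cohort_config()].
#' @return A list: `panels` (tibble, two rows per patient) and `truth`
#'   (`patient_id`, `responder`).
#' @export
gen_flow_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_patients
    ids <- sprintf("PT%03d", seq_len(n))
    n_resp <- round(n * cfg$responder_fraction)
    responder <- seq_len(n) %in% sample.int(n, n_resp)
    base <- tibble::tibble(
      patient_id = ids,
      pct_cd8_of_t = runif(n, 10, 30),
      pct_dp_of_cd8 = runif(n, 3, 15),
      pct_ki67_of_dp = runif(n, 2, 10)
    )
    lift <- function(resp, fold) ifelse(resp, fold, 1)
    post <- base |>
      dplyr::mutate(
        pct_cd8_of_t = pmin(100, pct_cd8_of_t *
          lift(responder, cfg$cd8_fold_responder) * lognormal_noise(n, cfg$noise_cv)),
        pct_dp_of_cd8 = pmin(100, pct_dp_of_cd8 *
          lift(responder, cfg$dp_fold_responder) * lognormal_noise(n, cfg$noise_cv)),
        pct_ki67_of_dp = pmin(100, pct_ki67_of_dp *
          lift(responder, cfg$dp_fold_responder) * lognormal_noise(n, cfg$noise_cv))
      )
    panels <- dplyr::bind_rows(
      dplyr::mutate(base, timepoint = "baseline"),
      dplyr::mutate(post, timepoint = "DOS")
    ) |>
      dplyr::select(patient_id, timepoint, dplyr::everything()) |>
      dplyr::arrange(patient_id, timepoint)
    list(panels = panels,
         truth = tibble::tibble(patient_id = ids, responder = responder))
  })
}

#' Generate a peripheral-blood proliferation time course
#'
#' Emits panels at baseline, D8, D12, D19, D34 and D55 with planted
#' fold-versus-baseline profiles that peak at D12: `ki67_cd4_fold` for Ki-67+
#' CD4 Tconv, the midpoint of `cd8_blood_fold_range` for Ki-67+ CD8 cells and
#' `plasmablast_fold` for plasmablasts, decaying back towards baseline by
#' D34-D55; %CD8 of T stays flat. Noise as in [gen_flow_cohort()].
#'
#' @param cfg A [cohort_config()].
#' @return A panels tibble (one row per patient x timepoint).
#' @export
gen_flow_timecourse <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  withr::with_seed(cfg$seed + 1L, {
    n <- cfg$n_patients
    ids <- sprintf("PT%03d", seq_len(n))
    tps <- c("baseline", "D8", "D12", "D19", "D34", "D55")
    cd8_peak <- mean(cfg$cd8_blood_fold_range)
    shape <- c(1, 0.35, 1, 0.65, 0.12, 0.02) # fraction of the log-scale peak
    profile <- function(peak) c(1, exp(log(peak) * shape[-1]))
    profiles <- list(
      pct_ki67_cd4 = profile(cfg$ki67_cd4_fold),
      pct_ki67_cd8 = profile(cd8_peak),
      pct_plasmablast = profile(cfg$plasmablast_fold),
      pct_cd8_of_t = rep(1, 6)
    )
    base <- list(
      pct_ki67_cd4 = runif(n, 2, 6),
      pct_ki67_cd8 = runif(n, 2, 6),
      pct_plasmablast = runif(n, 0.5, 2),
      pct_cd8_of_t = runif(n, 15, 30)
    )
    purrr::map_dfr(seq_along(tps), function(i) {
      row <- tibble::tibble(patient_id = ids, timepoint = tps[i])
      for (sub in names(profiles)) {
        fold <- profiles[[sub]][i]
        noise <- if (tps[i] == "baseline") 1 else lognormal_noise(n, cfg$noise_cv)
        row[[sub]] <- pmin(100, base[[sub]] * fold * noise)
      }
      row
    }) |>
      dplyr::arrange(patient_id, factor(timepoint, levels = tps))
  })
}

#' Generate somatic variants with known filter ground truth
#'
#' Builds `round(n * pass_fraction)` variants that satisfy every criterion of
#' the depth/VAF filter chain and the 2-of-4 caller concordance rule, and
#' fills the remainder with variants violating one to three named criteria.
#' Protein contexts span lengths 15-80 with mutations placed both internally
#' and near the termini, so window truncation is exercised. The sidecar truth
#' records each variant's pass flag and violated rules.
#'
#' @param n Number of variants (>= 1).
#' @param pass_fraction Target proportion passing all filters.
#' @param seed Integer seed.
#' @return A list: `variants` (tibble) and `truth` (`variant_id`, `passes`,
#'   `violations`).
#' @export
gen_variants <- function(n = 100, pass_fraction = 0.3, seed = 1) {
  stopifnot(n >= 1)
  check_proportion(pass_fraction, "pass_fraction")
  withr::with_seed(seed, {
    n_pass <- round(n * pass_fraction)
    passes <- seq_len(n) <= n_pass
    aa <- names(AA_CODON)
    rule_pool <- c("tumor_depth", "normal_depth", "tumor_vaf", "vaf_ratio", "callers")
    rows <- purrr::map(seq_len(n), function(i) {
      len <- sample(15:80, 1)
      ctx <- paste(sample(aa, len, replace = TRUE), collapse = "")
      pos <- if (runif(1) < 0.25) sample(c(1:4, (len - 3):len), 1) else sample(seq_len(len), 1)
      ref <- substr(ctx, pos, pos)
      alt <- sample(setdiff(aa, ref), 1)
      v <- list(
        gene = sprintf("GENE%03d", sample.int(500, 1)),
        protein_context = ctx, position = pos, ref_aa = ref, alt_aa = alt,
        tumor_depth = sample(11:200, 1),
        normal_depth = sample(11:200, 1),
        tumor_vaf = runif(1, 0.10, 0.6),
        normal_vaf = 0,
        callers = paste(sample(KNOWN_CALLERS, sample(2:4, 1)), collapse = ";"),
        fpkm = rlnorm(1, meanlog = 3.5, sdlog = 1.5)
      )
      if (runif(1) < 0.5) v$normal_vaf <- v$tumor_vaf / runif(1, 5, 50)
      viol <- character(0)
      if (!passes[i]) {
        viol <- sample(rule_pool, sample(1:3, 1))
        if ("tumor_depth" %in% viol) v$tumor_depth <- sample(0:10, 1)
        if ("normal_depth" %in% viol) v$normal_depth <- sample(0:10, 1)
        if ("tumor_vaf" %in% viol) {
          v$tumor_vaf <- runif(1, 0.005, 0.095)
          v$normal_vaf <- 0 # keep the ratio criterion satisfied
        }
        if ("vaf_ratio" %in% viol) {
          v$normal_vaf <- v$tumor_vaf / runif(1, 1.05, 4.5)
        }
        if ("callers" %in% viol) {
          v$callers <- sample(KNOWN_CALLERS, 1)
        }
      }
      v$violations <- paste(sort(viol), collapse = ";")
      v
    })
    variants <- purrr::map_dfr(rows, function(v) {
      tibble::as_tibble(v[setdiff(names(v), "violations")])
    })
    variants$variant_id <- sprintf("var%04d", seq_len(n))
    truth <- tibble::tibble(
      variant_id = variants$variant_id,
      passes = passes,
      violations = vapply(rows, function(v) v$violations, character(1))
    )
    # shuffle so pass/fail order carries no information
    ord <- sample.int(n)
    list(variants = variants[ord, ], truth = truth[ord, ])
  })
}

#' Generate two-group exponential survival data
#'
#' Event times are exponential per group with independent exponential
#' censoring: non-responders at `base_hazard` events/month, responders at
#' `base_hazard * hazard_ratio`. `hazard_ratio = 0` yields a responder group
#' with no events; `censor_rate = 0` disables censoring.
#'
#' @param n_per_group Patients per group.
#' @param hazard_ratio Responder-vs-non-responder hazard ratio (>= 0).
#' @param censor_rate Exponential censoring rate per month (>= 0).
#' @param seed Integer seed.
#' @param base_hazard Non-responder event rate per month (default 0.02).
#' @return A survival tibble: `patient_id`, `time`, `event`, `group`.
#' @export
gen_survival <- function(n_per_group = 100, hazard_ratio = 1,
                         censor_rate = 0.01, seed = 1, base_hazard = 0.02) {
  stopifnot(n_per_group >= 1, hazard_ratio >= 0, censor_rate >= 0,
            base_hazard > 0)
  withr::with_seed(seed, {
    draw <- function(n, rate) if (rate == 0) rep(Inf, n) else rexp(n, rate)
    one_group <- function(group, rate, offset) {
      t_event <- draw(n_per_group, rate)
      t_cens <- draw(n_per_group, censor_rate)
      tibble::tibble(
        patient_id = sprintf("PT%04d", offset + seq_len(n_per_group)),
        time = pmin(t_event, t_cens),
        event = is.finite(t_event) & t_event <= t_cens,
        group = group
      )
    }
    dplyr::bind_rows(
      one_group("responder", base_hazard * hazard_ratio, 0L),
      one_group("non_responder", base_hazard, n_per_group)
    )
  })
}

#' Generate multiplex-IHC ROI densities with planted structure
#'
#' Six ROIs per patient x timepoint x compartment x phenotype. CD3 density is
#' higher in stroma than tumor at both timepoints (the usual HNSCC pattern);
#' the proliferating CD8 phenotype (Ki67_CD103_CD8) increases post-treatment
#' by `tumor_fold` in the tumor compartment of responders only, with a
#' near-null `stroma_fold` everywhere else. ROI-to-ROI variation is
#' lognormal at `roi_cv`.
#'
#' @param truth Tibble `patient_id`, `responder` (e.g. from
#'   [gen_flow_cohort()]).
#' @param seed Integer seed.
#' @param tumor_fold Responder post/pre fold in tumor (default 3.4).
#' @param stroma_fold Post/pre fold in stroma (default 1.12).
#' @param roi_cv ROI-level coefficient of variation (default 0.3).
#' @return An ROI tibble (`patient_id`, `timepoint`, `compartment`,
#'   `phenotype`, `roi_index`, `density`, `roi_area`).
#' @export
gen_roi_cohort <- function(truth, seed = 1, tumor_fold = 3.4,
                           stroma_fold = 1.12, roi_cv = 0.3) {
  stopifnot(all(c("patient_id", "responder") %in% names(truth)))
  withr::with_seed(seed, {
    mean_density <- list(
      CD3 = c(tumor = 300, stroma = 900),
      Ki67_CD103_CD8 = c(tumor = 25, stroma = 40)
    )
    grid <- tidyr::expand_grid(
      patient_id = truth$patient_id,
      timepoint = c("pre", "post"),
      compartment = c("tumor", "stroma"),
      phenotype = names(mean_density),
      roi_index = 1:6
    ) |>
      dplyr::left_join(truth, by = "patient_id")
    base <- purrr::map2_dbl(grid$phenotype, grid$compartment,
                            function(ph, cp) mean_density[[ph]][[cp]])
    fold <- ifelse(
      grid$phenotype == "Ki67_CD103_CD8" & grid$timepoint == "post",
      ifelse(grid$compartment == "tumor" & grid$responder, tumor_fold, stroma_fold),
      1
    )
    grid |>
      dplyr::mutate(
        density = base * fold * lognormal_noise(nrow(grid), roi_cv),
        roi_area = 0.36
      ) |>
      dplyr::select(-responder)
  })
}

#' Generate an ELISpot plate with a planted DP-restricted response
#'
#' Wells for DN, SP, DP and memory subsets against a test stimulus, a mock
#' negative control and an anti-CD3 positive control. The DP subset responds
#' to the stimulus well above the 100-SFC positivity cutoff; bystander
#' subsets stay below it.
#'
#' @param seed Integer seed.
#' @param dp_mean_sfc Mean SFC of the responding DP wells (default 400).
#' @return Tibble: `well_id`, `subset`, `stimulus`, `sfc`.
#' @export
gen_elispot_plate <- function(seed = 1, dp_mean_sfc = 400) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      subset = c("DN", "SP", "DP", "memory"),
      stimulus = c("peptide", "mock", "anti_CD3"),
      replicate = 1:2
    )
    mu <- dplyr::case_when(
      grid$stimulus == "anti_CD3" ~ 600,
      grid$stimulus == "mock" ~ 8,
      grid$subset == "DP" ~ dp_mean_sfc,
      TRUE ~ 20
    )
    grid |>
      dplyr::mutate(
        well_id = sprintf("W%02d", dplyr::row_number()),
        sfc = stats::rpois(dplyr::n(), mu)
      ) |>
      dplyr::select(well_id, subset, stimulus, sfc)
  })
}
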