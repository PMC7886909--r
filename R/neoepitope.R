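KNOWN_CALLERS <- c("mutect", "somaticsniper", "strelka", "varscan")

split_callers <- function(x) {
  strsplit(ifelse(is.na(x) | x == "", "", x), "[;,]\\s*")
}

validate_variants <- function(variants) {
  variants <- tibble::as_tibble(variants)
  needed <- c("gene", "protein_context", "position", "ref_aa", "alt_aa",
              "tumor_depth", "normal_depth", "tumor_vaf", "normal_vaf",
              "callers", "fpkm")
  missing <- setdiff(needed, names(variants))
  if (length(missing) > 0) {
    abort(paste0("variant table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tilmonitor_bad_format")
  }
  bad_vaf <- which(variants$tumor_vaf < 0 | variants$tumor_vaf > 1 |
                     variants$normal_vaf < 0 | variants$normal_vaf > 1)
  if (length(bad_vaf) > 0) {
    abort(paste0("VAF outside [0, 1] in variant row(s): ",
                 paste(head(bad_vaf, 5), collapse = ", ")),
          class = "tilmonitor_bad_value")
  }
  if (!"variant_id" %in% names(variants)) {
    variants$variant_id <- sprintf("var%04d", seq_len(nrow(variants)))
  }
  variants
}

#' Filter somatic variants on depth and allele-frequency criteria
#'
#' A variant is kept iff tumor depth > `min_tumor_depth` (strict), normal
#' depth > `min_normal_depth` (strict), tumor VAF >= `min_tumor_vaf`, and the
#' tumor/normal VAF ratio >= `min_vaf_ratio`, where a normal VAF of exactly 0
#' passes the ratio criterion by definition (a germline-clean variant has an
#' infinite ratio). Every failed criterion is named per rejected record.
#'
#' @param variants Variant tibble; see [gen_variants()] for the columns.
#' @param min_tumor_depth,min_normal_depth Strict lower bounds on read depth
#'   (default 10: "more than 10 reads").
#' @param min_tumor_vaf Inclusive lower bound on tumor VAF (default 0.10).
#' @param min_vaf_ratio Inclusive lower bound on tumor/normal VAF ratio
#'   (default 5).
#' @return A list with `kept` (passing rows) and `rejected` (failing rows
#'   plus a `reasons` column listing every violated criterion).
#' @export
filter_variants <- function(variants, min_tumor_depth = 10,
                            min_normal_depth = 10, min_tumor_vaf = 0.10,
                            min_vaf_ratio = 5) {
  variants <- validate_variants(variants)
  reasons <- purrr::pmap_chr(
    list(variants$tumor_depth, variants$normal_depth,
         variants$tumor_vaf, variants$normal_vaf),
    function(td, nd, tv, nv) {
      r <- character(0)
      if (!(td > min_tumor_depth)) r <- c(r, sprintf("tumor_depth<=%d", min_tumor_depth))
      if (!(nd > min_normal_depth)) r <- c(r, sprintf("normal_depth<=%d", min_normal_depth))
      if (!(tv >= min_tumor_vaf)) r <- c(r, sprintf("tumor_vaf<%.2f", min_tumor_vaf))
      ratio_ok <- nv == 0 || tv / nv >= min_vaf_ratio
      if (!ratio_ok) r <- c(r, sprintf("vaf_ratio<%g", min_vaf_ratio))
      paste(r, collapse = ";")
    }
  )
  pass <- reasons == ""
  list(
    kept = variants[pass, , drop = FALSE],
    rejected = dplyr::mutate(variants[!pass, , drop = FALSE],
                             reasons = reasons[!pass])
  )
}

#' Keep variants called by at least k mutation callers
#'
#' @param variants Variant tibble with a `callers` column (semicolon- or
#'   comma-separated subset of mutect, somaticsniper, strelka, varscan).
#' @param k Minimum number of concordant callers (default 2 of 4).
#' @return A list with `kept` and `rejected` tibbles.
#' @export
caller_concordance <- function(variants, k = 2) {
  stopifnot(k >= 1)
  variants <- validate_variants(variants)
  sets <- split_callers(variants$callers)
  unknown <- setdiff(unique(unlist(sets)), KNOWN_CALLERS)
  if (length(unknown) > 0) {
    abort(paste0("unknown mutation caller name(s): ",
                 paste(unknown, collapse = ", ")),
          class = "tilmonitor_bad_value")
  }
  n_callers <- vapply(sets, function(s) length(unique(s)), integer(1))
  pass <- n_callers >= k
  list(
    kept = variants[pass, , drop = FALSE],
    rejected = dplyr::mutate(variants[!pass, , drop = FALSE],
                             reasons = sprintf("callers<%d", k))
  )
}

#' Build mutant 25-mer neoepitope windows around each variant
#'
#' Extracts up to `flank` residues either side of the mutated position from
#' the reference protein context (a full 25-mer when 12 residues flank both
#' sides; truncated at the protein termini otherwise, never dropping the
#' mutated residue) and substitutes the alternate amino acid. Only single
#' amino-acid substitutions are supported; indel/frameshift records are
#' rejected with a clear message.
#'
#' @param variants Validated variant tibble.
#' @param flank Residues kept either side of the mutation (default 12,
#'   giving 25-mers).
#' @return The input tibble with `window25` (mutant window sequence) and
#'   `mut_index_in_window` (1-based position of the substituted residue).
#' @export
build_window <- function(variants, flank = 12) {
  variants <- validate_variants(variants)
  n <- nrow(variants)
  win <- character(n)
  idx <- integer(n)
  for (i in seq_len(n)) {
    ctx <- variants$protein_context[i]
    pos <- variants$position[i]
    len <- nchar(ctx)
    if (pos < 1 || pos > len) {
      abort(sprintf("variant %s: position %d outside protein context (length %d)",
                    variants$variant_id[i], pos, len),
            class = "tilmonitor_bad_value")
    }
    if (nchar(variants$ref_aa[i]) != 1 || nchar(variants$alt_aa[i]) != 1) {
      abort(sprintf(paste0("variant %s: only single amino-acid substitutions ",
                           "are supported (indels/frameshifts are out of scope)"),
                    variants$variant_id[i]),
            class = "tilmonitor_bad_value")
    }
    if (substr(ctx, pos, pos) != variants$ref_aa[i]) {
      abort(sprintf("variant %s: ref_aa '%s' does not match context residue '%s' at position %d",
                    variants$variant_id[i], variants$ref_aa[i],
                    substr(ctx, pos, pos), pos),
            class = "tilmonitor_bad_value")
    }
    from <- max(1, pos - flank)
    to <- min(len, pos + flank)
    w <- substr(ctx, from, to)
    mi <- pos - from + 1
    substr(w, mi, mi) <- variants$alt_aa[i]
    win[i] <- w
    idx[i] <- mi
  }
  dplyr::mutate(variants, window25 = win, mut_index_in_window = idx)
}

peptides_for_window <- function(window, mut_index, lengths = 8:11) {
  len <- nchar(window)
  if (len < min(lengths)) {
    return(tibble::tibble(start = integer(0), length = integer(0),
                          sequence = character(0)))
  }
  out <- purrr::map_dfr(sort(unique(as.integer(lengths))), function(L) {
    if (len < L) return(NULL)
    starts <- seq.int(max(1, mut_index - L + 1), min(mut_index, len - L + 1))
    tibble::tibble(start = starts, length = L,
                   sequence = substring(window, starts, starts + L - 1))
  })
  out <- dplyr::arrange(out, start, length)
  out[!duplicated(out$sequence), , drop = FALSE]
}

#' Enumerate mutation-spanning 8-11mer peptides from each window
#'
#' All distinct substrings of lengths 8-11 of the mutant window that cover
#' the mutated residue, deduplicated on sequence, in deterministic
#' (start, length) order. Windows shorter than 8 residues yield an empty
#' peptide set with a warning.
#'
#' @param candidates Tibble from [build_window()].
#' @param lengths Peptide lengths to enumerate (default 8:11).
#' @return The input with a `peptides` list-column of tibbles
#'   (`start`, `length`, `sequence`).
#' @export
enumerate_peptides <- function(candidates, lengths = 8:11) {
  stopifnot(all(c("window25", "mut_index_in_window") %in% names(candidates)))
  peps <- purrr::map2(candidates$window25, candidates$mut_index_in_window,
                      peptides_for_window, lengths = lengths)
  short <- nchar(candidates$window25) < min(lengths)
  if (any(short)) {
    warn(paste0("window(s) shorter than ", min(lengths),
                " residues yield no peptides: ",
                paste(candidates$variant_id[short], collapse = ", ")))
  }
  dplyr::mutate(candidates, peptides = peps)
}

#' Flag candidates whose transcript level exceeds an FPKM threshold
#'
#' Prioritized means FPKM strictly exceeding the threshold (default 100);
#' output is ordered prioritized-first, then FPKM descending.
#'
#' @param candidates Candidate tibble with an `fpkm` column.
#' @param threshold Non-negative FPKM threshold (default 100).
#' @return The tibble with a `prioritized` logical column, reordered.
#' @export
prioritize_fpkm <- function(candidates, threshold = 100) {
  stopifnot(threshold >= 0)
  candidates |>
    dplyr::mutate(prioritized = fpkm > threshold) |>
    dplyr::arrange(dplyr::desc(prioritized), dplyr::desc(fpkm), variant_id)
}

#' Deterministic stand-in binding scorer for tests and dry runs
#'
#' Maps a peptide sequence to a reproducible pseudo-affinity in (0, 10) via a
#' fixed polynomial hash of its characters; roughly 5% of random peptides
#' score at or below the default 0.5 cutoff. It carries no biology — real
#' predictions should be supplied through the `scorer` argument of
#' [rank_candidates()] (any vectorized peptide -> score function, e.g. a
#' wrapper around an external MHC binding predictor).
#'
#' @param peptides Character vector of peptide sequences.
#' @return Numeric scores, one per peptide.
#' @export
stub_affinity_scorer <- function(peptides) {
  vapply(peptides, function(p) {
    codes <- utf8ToInt(p)
    h <- 0
    for (c in codes) h <- (h * 31 + c) %% 100003
    (h %% 10000) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score peptides and keep candidates with at least one strong binder
#'
#' Applies a pluggable scorer to every enumerated peptide and keeps
#' candidates with at least one peptide scoring at or below `cutoff`
#' (inclusive). The cutoff is unit-agnostic: it applies to whatever scale the
#' scorer emits (predicted affinity in nM, percentile rank, ...); the default
#' 0.5 matches a stringent predicted-affinity screen.
#'
#' @param candidates Tibble from [enumerate_peptides()].
#' @param scorer Function mapping a character vector of peptides to numeric
#'   scores. Default [stub_affinity_scorer()].
#' @param cutoff Inclusive upper bound on the score (default 0.5).
#' @return A list: `candidates` (surviving rows with `best_score` and a
#'   `binding` list-column of scored, passing peptides) and `scores` (long
#'   tibble of every peptide with its score and pass flag).
#' @export
rank_candidates <- function(candidates, scorer = stub_affinity_scorer,
                            cutoff = 0.5) {
  stopifnot(is.function(scorer), cutoff > 0,
            "peptides" %in% names(candidates))
  scores_long <- purrr::map2_dfr(candidates$variant_id, candidates$peptides,
    function(id, peps) {
      if (nrow(peps) == 0) return(NULL)
      s <- tryCatch(scorer(peps$sequence), error = function(e) e)
      if (inherits(s, "error") || length(s) != nrow(peps) || anyNA(s)) {
        bad <- if (inherits(s, "error")) conditionMessage(s) else "invalid score"
        first <- peps$sequence[if (length(s) == nrow(peps)) which(is.na(s))[1] else 1]
        abort(paste0("scorer failed on peptide ", first, ": ", bad),
              class = "tilmonitor_scorer_error")
      }
      dplyr::mutate(peps, variant_id = id, score = s, passes = s <= cutoff)
    })
  best <- scores_long |>
    dplyr::group_by(variant_id) |>
    dplyr::summarise(best_score = min(score), .groups = "drop")
  out <- candidates |>
    dplyr::left_join(best, by = "variant_id") |>
    dplyr::mutate(survives = !is.na(best_score) & best_score <= cutoff)
  surv <- out[out$survives, , drop = FALSE]
  surv$binding <- lapply(surv$variant_id, function(id) {
    scores_long[scores_long$variant_id == id & scores_long$passes, , drop = FALSE]
  })
  list(candidates = surv, scores = scores_long)
}

#' Run the full variant-to-candidate chain
#'
#' Depth/VAF filters, caller concordance, window construction, peptide
#' enumeration, FPKM prioritization and binding-score ranking, in order. The
#' depth/VAF and caller filters commute, so their order does not affect the
#' kept set.
#'
#' @param variants Variant tibble.
#' @param min_callers Minimum concordant callers (default 2).
#' @param fpkm_threshold FPKM prioritization threshold (default 100).
#' @param binding_cutoff Inclusive score cutoff (default 0.5).
#' @param scorer Peptide scorer (default [stub_affinity_scorer()]).
#' @return A list: `candidates` (surviving, prioritized-ordered), `scores`,
#'   `filtered` (post-filter pre-scoring candidates), `rejected` (tibble of
#'   rejected variants with reasons).
#' @export
neoepitope_chain <- function(variants, min_callers = 2, fpkm_threshold = 100,
                             binding_cutoff = 0.5,
                             scorer = stub_affinity_scorer) {
  f1 <- filter_variants(variants)
  f2 <- caller_concordance(f1$kept, k = min_callers)
  rejected <- dplyr::bind_rows(f1$rejected, f2$rejected)
  if (nrow(f2$kept) == 0) {
    return(list(candidates = f2$kept, scores = tibble::tibble(),
                filtered = f2$kept, rejected = rejected))
  }
  cands <- f2$kept |>
    build_window() |>
    enumerate_peptides() |>
    prioritize_fpkm(threshold = fpkm_threshold)
  ranked <- rank_candidates(cands, scorer = scorer, cutoff = binding_cutoff)
  list(candidates = ranked$candidates, scores = ranked$scores,
       filtered = cands, rejected = rejected)
}

#' Write mutant peptides as FASTA
#'
#' One record per scored candidate peptide, headers
#' `>variantid|gene|start|length`.
#'
#' @param scores Long peptide tibble from [rank_candidates()] (`scores`).
#' @param candidates Candidate tibble supplying `gene` per `variant_id`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(scores, candidates, path) {
  genes <- setNames(candidates$gene, candidates$variant_id)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(scores))) {
    writeLines(sprintf(">%s|%s|%d|%d", scores$variant_id[i],
                       genes[[scores$variant_id[i]]],
                       scores$start[i], scores$length[i]), con)
    writeLines(scores$sequence[i], con)
  }
  invisible(path)
}
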