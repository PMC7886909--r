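variant_row <- function(ctx, pos, alt = NULL, id = "v1", td = 100, nd = 100,
                        tv = 0.4, nv = 0, callers = "mutect;strelka",
                        fpkm = 50) {
  ref <- substr(ctx, pos, pos)
  alt <- alt %||% setdiff(c("A", "W"), ref)[1]
  tibble::tibble(
    variant_id = id, gene = "G1", protein_context = ctx, position = pos,
    ref_aa = ref, alt_aa = alt, tumor_depth = td, normal_depth = nd,
    tumor_vaf = tv, normal_vaf = nv, callers = callers, fpkm = fpkm
  )
}

test_that("depth and VAF filters honour their stated boundaries", {
  ctx <- strrep("L", 30)
  v <- dplyr::bind_rows(
    variant_row(ctx, 15, id = "ok"),
    variant_row(ctx, 15, id = "td_eq10", td = 10),       # strict >10 fails
    variant_row(ctx, 15, id = "nd_eq10", nd = 10),
    variant_row(ctx, 15, id = "tv_eq_p10", tv = 0.10),   # >= passes
    variant_row(ctx, 15, id = "tv_low", tv = 0.09),
    variant_row(ctx, 15, id = "ratio4", tv = 0.4, nv = 0.1), # ratio 4 < 5
    variant_row(ctx, 15, id = "ratio5", tv = 0.5, nv = 0.1), # ratio 5 passes
    variant_row(ctx, 15, id = "nv_zero", tv = 0.12, nv = 0)  # 0 passes
  )
  out <- filter_variants(v)
  expect_setequal(out$kept$variant_id, c("ok", "tv_eq_p10", "ratio5", "nv_zero"))
  reasons <- setNames(out$rejected$reasons, out$rejected$variant_id)
  expect_match(reasons[["td_eq10"]], "tumor_depth<=10")
  expect_match(reasons[["ratio4"]], "vaf_ratio<5")
  # a doubly-failing record lists both criteria
  multi <- filter_variants(variant_row(ctx, 15, td = 5, tv = 0.05))
  expect_match(multi$rejected$reasons, "tumor_depth<=10;tumor_vaf<0.10")
  expect_error(filter_variants(variant_row(ctx, 15, tv = 1.5)),
               class = "tilmonitor_bad_value")
})

test_that("caller concordance keeps >= k of the four known callers", {
  ctx <- strrep("K", 20)
  v <- dplyr::bind_rows(
    variant_row(ctx, 10, id = "one", callers = "mutect"),
    variant_row(ctx, 10, id = "two", callers = "mutect;strelka"),
    variant_row(ctx, 10, id = "four", callers = "mutect;somaticsniper;strelka;varscan")
  )
  out <- caller_concordance(v, k = 2)
  expect_setequal(out$kept$variant_id, c("two", "four"))
  expect_equal(nrow(caller_concordance(v, k = 4)$kept), 1)
  expect_error(caller_concordance(variant_row(ctx, 10, callers = "gatk")),
               class = "tilmonitor_bad_value")
  # brute-force count on a generated fixture
  gv <- gen_variants(10, 0.5, seed = 2)
  counts <- lengths(strsplit(gv$variants$callers, ";"))
  expect_equal(nrow(caller_concordance(gv$variants, k = 2)$kept),
               sum(counts >= 2))
})

test_that("depth/VAF and caller filters commute", {
  gv <- gen_variants(60, 0.4, seed = 8)
  ab <- caller_concordance(filter_variants(gv$variants)$kept, 2)$kept
  ba <- filter_variants(caller_concordance(gv$variants, 2)$kept)$kept
  expect_setequal(ab$variant_id, ba$variant_id)
  # and row order of the input is irrelevant
  shuffled <- gv$variants[sample.int(nrow(gv$variants)), ]
  ab2 <- caller_concordance(filter_variants(shuffled)$kept, 2)$kept
  expect_setequal(ab2$variant_id, ab$variant_id)
})

test_that("windows are centered, truncated at termini, and mutation-checked", {
  ctx25 <- paste(rep(c("A", "R", "N", "D", "C"), 5), collapse = "")
  w <- build_window(variant_row(ctx25, 13, alt = "W"))
  expect_equal(nchar(w$window25), 25)
  expect_equal(w$mut_index_in_window, 13)
  expect_equal(substr(w$window25, 13, 13), "W")
  # flanks removed, rest identical to context
  expect_equal(substr(w$window25, 1, 12), substr(ctx25, 1, 12))

  ctx100 <- strrep("LIVE", 25)
  w5 <- build_window(variant_row(ctx100, 5, alt = "W"))
  expect_equal(nchar(w5$window25), 17) # 4 left + 1 + 12 right
  expect_equal(w5$mut_index_in_window, 5)
  w50 <- build_window(variant_row(ctx100, 50, alt = "W"))
  expect_equal(nchar(w50$window25), 25)
  expect_equal(w50$mut_index_in_window, 13)
  # truncation never drops the mutated residue
  wend <- build_window(variant_row(ctx100, 100, alt = "W"))
  expect_equal(substr(wend$window25, wend$mut_index_in_window,
                      wend$mut_index_in_window), "W")

  bad <- variant_row(ctx100, 5, alt = "W")
  bad$ref_aa <- "Q"
  expect_error(build_window(bad), "does not match",
               class = "tilmonitor_bad_value")
  indel <- variant_row(ctx100, 5)
  indel$alt_aa <- "WW"
  expect_error(build_window(indel), "single amino-acid",
               class = "tilmonitor_bad_value")
})

test_that("peptide enumeration matches the brute-force oracle", {
  ctx25 <- paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G"), 25,
                        replace = TRUE), collapse = "")
  central <- enumerate_peptides(build_window(variant_row(ctx25, 13, alt = "W")))
  peps <- central$peptides[[1]]
  expect_equal(nrow(peps), 38) # 8 + 9 + 10 + 11 spanning windows
  expect_setequal(peps$sequence,
                  naive_mut_peptides(central$window25, 13))
  # every peptide spans the mutated index
  expect_true(all(peps$start <= 13 & 13 <= peps$start + peps$length - 1))

  edge <- enumerate_peptides(build_window(variant_row(strrep("LIVE", 25), 1,
                                                      alt = "W")))
  expect_equal(nrow(edge$peptides[[1]]), 4) # one per length

  # random windows vs oracle
  set.seed(3)
  for (i in 1:30) {
    len <- sample(8:40, 1)
    ctx <- paste(sample(c("A", "G", "L", "S", "T", "V", "K", "R"), len,
                        replace = TRUE), collapse = "")
    pos <- sample(seq_len(len), 1)
    cand <- enumerate_peptides(build_window(variant_row(ctx, pos, alt = "W")))
    expect_setequal(cand$peptides[[1]]$sequence,
                    naive_mut_peptides(cand$window25,
                                       cand$mut_index_in_window))
  }
  # homopolymer window: dedup equals oracle's unique set
  homo <- enumerate_peptides(build_window(variant_row(strrep("A", 25), 13,
                                                      alt = "W")))
  expect_setequal(homo$peptides[[1]]$sequence,
                  naive_mut_peptides(homo$window25, 13))
})

test_that("emitted peptides differ from reference in exactly one residue", {
  set.seed(11)
  ctx <- paste(sample(c("A", "G", "L", "S"), 40, replace = TRUE), collapse = "")
  v <- variant_row(ctx, 20, alt = "W")
  cand <- enumerate_peptides(build_window(v))
  ref_window <- substr(ctx, 20 - cand$mut_index_in_window + 1,
                       20 - cand$mut_index_in_window + nchar(cand$window25))
  for (i in seq_len(nrow(cand$peptides[[1]]))) {
    p <- cand$peptides[[1]][i, ]
    ref_pep <- substr(ref_window, p$start, p$start + p$length - 1)
    diffs <- sum(strsplit(p$sequence, "")[[1]] != strsplit(ref_pep, "")[[1]])
    expect_equal(diffs, 1)
  }
})

test_that("short windows warn and yield empty peptide sets", {
  short <- variant_row(strrep("A", 6), 3, alt = "W")
  expect_warning(out <- enumerate_peptides(build_window(short)),
                 "shorter than 8")
  expect_equal(nrow(out$peptides[[1]]), 0)
})

test_that("FPKM prioritization uses a strict threshold and sorts", {
  ctx <- strrep("L", 30)
  v <- dplyr::bind_rows(
    variant_row(ctx, 15, id = "at100", fpkm = 100),
    variant_row(ctx, 15, id = "hi", fpkm = 250),
    variant_row(ctx, 15, id = "lo", fpkm = 5)
  )
  out <- prioritize_fpkm(v)
  expect_equal(out$prioritized, c(TRUE, FALSE, FALSE))
  expect_equal(out$variant_id, c("hi", "at100", "lo")) # independent sort order
})

test_that("ranking keeps candidates with any peptide at or below cutoff", {
  ctx <- strrep("K", 30)
  cands <- enumerate_peptides(build_window(dplyr::bind_rows(
    variant_row(ctx, 15, id = "a", alt = "W"),
    variant_row(ctx, 15, id = "b", alt = "Y")
  )))
  at_cutoff <- rank_candidates(cands, scorer = function(p) rep(0.5, length(p)))
  expect_setequal(at_cutoff$candidates$variant_id, c("a", "b")) # inclusive
  above <- rank_candidates(cands, scorer = function(p) rep(1.5, length(p)))
  expect_equal(nrow(above$candidates), 0)
  # stub scorer matches exhaustive evaluation
  ranked <- rank_candidates(cands, cutoff = 2)
  exhaustive <- unlist(lapply(cands$peptides, function(p)
    min(stub_affinity_scorer(p$sequence))))
  expect_setequal(ranked$candidates$variant_id,
                  cands$variant_id[exhaustive <= 2])
  expect_error(rank_candidates(cands, scorer = function(p) stop("boom")),
               class = "tilmonitor_scorer_error")
})

test_that("the stub scorer is deterministic and seed-free", {
  p <- c("SIINFEKL", "KVAELVHFL")
  expect_identical(stub_affinity_scorer(p), stub_affinity_scorer(p))
  expect_true(all(stub_affinity_scorer(p) >= 0 & stub_affinity_scorer(p) < 10))
})

test_that("gen_variants ground truth matches the filter chain exactly", {
  gv <- gen_variants(100, 0.3, seed = 5)
  kept <- caller_concordance(filter_variants(gv$variants)$kept, 2)$kept
  expect_setequal(kept$variant_id, gv$truth$variant_id[gv$truth$passes])
  expect_equal(nrow(kept), sum(gv$truth$passes))
  # boundary pass fractions
  all_pass <- gen_variants(20, 1, seed = 1)
  expect_equal(nrow(caller_concordance(
    filter_variants(all_pass$variants)$kept, 2)$kept), 20)
  none_pass <- gen_variants(20, 0, seed = 1)
  expect_equal(nrow(caller_concordance(
    filter_variants(none_pass$variants)$kept, 2)$kept), 0)
})

test_that("the full chain runs and writes peptide FASTA", {
  gv <- gen_variants(40, 0.5, seed = 4)
  out <- neoepitope_chain(gv$variants, binding_cutoff = 2)
  expect_equal(nrow(out$filtered), sum(gv$truth$passes))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_peptides_fasta(out$scores, out$filtered, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, ">")), nrow(out$scores))
})
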