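fp <- filter_params()

test_that("the documented boundary cases pass and fail as specified", {
  # exactly 40% variant reads, one per strand, depth 5 in both strains: PASS
  evo <- make_alt_site("G", "T", n_alt = 2, depth = 5, alt_fwd = 1)
  anc <- make_alt_site("G", "T", n_alt = 0, depth = 5)
  res <- call_site(anc, evo, fp)
  expect_true(res$pass)
  expect_length(res$reasons, 0)
  expect_equal(res$call$alt, "T")
  expect_equal(res$call$evolved_frac, 0.4)

  # 2/6 = 33.3% just below the threshold
  evo2 <- make_alt_site("G", "T", n_alt = 2, depth = 6, alt_fwd = 1)
  anc6 <- make_alt_site("G", "T", n_alt = 0, depth = 6)
  res2 <- call_site(anc6, evo2, fp)
  expect_false(res2$pass)
  expect_equal(res2$reasons, "LOW_EVOLVED_FRAC")

  # ancestor at 1/9 = 11.1% fails; 1/10 = 10.0% is inclusive and passes
  evo80 <- make_alt_site("G", "T", n_alt = 8, depth = 10, alt_fwd = 4)
  anc9 <- make_alt_site("G", "T", n_alt = 1, depth = 9)
  expect_equal(call_site(anc9, evo80, fp)$reasons, "HIGH_ANCESTOR_FRAC")
  anc10 <- make_alt_site("G", "T", n_alt = 1, depth = 10)
  expect_true(call_site(anc10, evo80, fp)$pass)

  # all variant reads on one strand
  evo_fwd <- make_alt_site("G", "T", n_alt = 4, depth = 5, alt_fwd = 4)
  anc5 <- make_alt_site("G", "T", n_alt = 0, depth = 5)
  expect_equal(call_site(anc5, evo_fwd, fp)$reasons, "STRAND_UNCONFIRMED")

  # two ambiguous calls at the site
  evoN <- make_alt_site("G", "T", n_alt = 4, depth = 10, alt_fwd = 2,
                        n_ambiguous = 2)
  anc8 <- make_alt_site("G", "T", n_alt = 0, depth = 10)
  expect_equal(call_site(anc8, evoN, fp)$reasons, "EXCESS_AMBIGUOUS")

  # no non-reference base at all
  ref_only <- make_alt_site("G", "T", n_alt = 0, depth = 8)
  expect_equal(call_site(anc8, ref_only, fp)$reasons, "NO_ALT")
})

test_that("every violated rule is reported, not only the first", {
  # evolved: 1/3 variant reads (33%), forward only, two deleted bases;
  # ancestor: 1/3 variant reads (33%), raw depth 3
  evo <- make_alt_site("G", "T", n_alt = 1, depth = 3, alt_fwd = 1,
                       n_deletion = 2)
  anc <- make_alt_site("G", "T", n_alt = 1, depth = 3)
  res <- call_site(anc, evo, fp)
  expect_false(res$pass)
  expect_setequal(res$reasons,
                  c("LOW_EVOLVED_FRAC", "HIGH_ANCESTOR_FRAC",
                    "LOW_DEPTH_ANCESTOR", "STRAND_UNCONFIRMED",
                    "EXCESS_DELETION"))
})

test_that("candidate-allele ties break alphabetically", {
  evo <- make_site("G", A_fwd = 2, A_rev = 2, T_fwd = 2, T_rev = 2,
                   G_fwd = 1, G_rev = 1)
  anc <- make_site("G", G_fwd = 5, G_rev = 5)
  expect_equal(call_site(anc, evo, fp)$call$alt, "A")
})

test_that("mismatched site pairs are contract errors", {
  a <- make_site("G", pos = 1, G_fwd = 5)
  b <- make_site("G", pos = 2, G_fwd = 5)
  expect_error(call_site(a, b, fp), "not position-aligned")
  c <- make_site("A", pos = 1, A_fwd = 5)
  expect_error(call_site(a, c, fp), "reference bases disagree")
})

test_that("call_site agrees with the rule-by-rule oracle on random sites", {
  pair <- random_site_pairs(2000, seed = 17)
  frame <- oracle_call_frame(pair$anc, pair$evo, fp)
  for (i in sample(2000, 200)) {
    got <- call_site(pair$anc[i, ], pair$evo[i, ], fp)
    ora <- oracle_call_site(pair$anc[i, ], pair$evo[i, ], fp)
    expect_identical(got$pass, ora$pass)
    expect_identical(sort(got$reasons), ora$reasons)
    expect_identical(frame$pass[i], ora$pass)
  }
})

test_that("tightening thresholds never adds a call", {
  pair <- random_site_pairs(3000, seed = 23)
  calls_at <- function(p) {
    res <- call_genome(pair$anc, pair$evo, p)
    paste(res$calls$pos, res$calls$alt)
  }
  base <- calls_at(filter_params(min_evolved_frac = 0.3, min_depth = 3))
  tighter_frac <- calls_at(filter_params(min_evolved_frac = 0.5,
                                         min_depth = 3))
  tighter_depth <- calls_at(filter_params(min_evolved_frac = 0.3,
                                          min_depth = 8))
  expect_true(all(tighter_frac %in% base))
  expect_true(all(tighter_depth %in% base))
})

test_that("call_genome tallies cover every compared site", {
  pair <- random_site_pairs(1000, seed = 31)
  res <- call_genome(pair$anc, pair$evo, fp)
  # sites either pass, or fail with >= 1 reason; NO_ALT sites are not in
  # rejections but are tallied
  expect_equal(res$n_compared, 1000)
  frame <- oracle_call_frame(pair$anc, pair$evo, fp)
  expect_equal(nrow(res$calls), sum(frame$pass))
  no_alt <- is.na(frame$alt)
  expect_equal(nrow(res$calls) + nrow(res$rejections) +
                 sum(no_alt & !frame$pass),
               1000)
  for (code in colnames(frame$fail)) {
    expect_equal(unname(res$tally[code]),
                 sum(frame$fail[, code] & !frame$pass))
  }
})

test_that("positions present in only one stream are skipped and tallied", {
  anc <- rbind(make_site("G", pos = 1, G_fwd = 3, G_rev = 3),
               make_site("G", pos = 2, G_fwd = 3, G_rev = 3))
  evo <- rbind(make_site("G", pos = 2, T_fwd = 3, T_rev = 3),
               make_site("G", pos = 3, T_fwd = 3, T_rev = 3))
  res <- call_genome(anc, evo, fp)
  expect_equal(res$n_compared, 1)
  expect_equal(unname(res$tally["ONLY_IN_ANCESTOR"]), 1L)
  expect_equal(unname(res$tally["ONLY_IN_EVOLVED"]), 1L)
  expect_error(call_genome(anc[2:1, ], evo, fp), "not sorted")
})

test_that("an empty evolved stream yields no calls and no tallies", {
  anc <- make_site("G", pos = 1, G_fwd = 3, G_rev = 3)
  res <- call_genome(anc, anc[0, ], fp)
  expect_equal(nrow(res$calls), 0)
  expect_equal(sum(res$tally[setdiff(names(res$tally),
                                     "ONLY_IN_ANCESTOR")]), 0L)
})

test_that("two evolved strains intersect exactly on shared-branch truth", {
  g <- generate_annotated_genome(20000, 0, 3)
  spec <- lineage_spec("(A,B);", c(A = 8, B = 6, "A,B" = 5),
                       gc_ta_weight = 0.9)
  pl <- plant_mutations(g, spec, seed = 3)
  anc_pu <- simulate_pileup(g, pileup_sim_params(40, 0, seed = 100))
  anc <- parse_pileup_lines(with(anc_pu, sprintf("%s\t%d\t%s\t%d\t%s\t%s",
                                                 chrom, pos, ref, depth,
                                                 bases, quals)))
  calls <- lapply(c("A", "B"), function(s) {
    pu <- simulate_pileup(g, pileup_sim_params(40, 0, seed = 100 + match(s, c("A","B"))),
                          strain_seq = pl$strain_seqs[[s]])
    lines <- with(pu, sprintf("%s\t%d\t%s\t%d\t%s\t%s", chrom, pos, ref,
                              depth, bases, quals))
    call_genome(anc, parse_pileup_lines(lines), fp, strain = s)$calls
  })
  shared_truth <- sort(pl$truth$pos[pl$truth$carriers == "A,B"])
  expect_equal(sort(intersect(calls[[1]]$pos, calls[[2]]$pos)), shared_truth)
  # noise-free: perfect recall and precision per strain
  for (i in 1:2) {
    s <- c("A", "B")[i]
    truth_s <- sort(pl$truth$pos[grepl(paste0("(^|,)", s, "(,|$)"),
                                       pl$truth$carriers)])
    expect_equal(sort(calls[[i]]$pos), truth_s)
  }
})

test_that("VCF output round-trips and is readable by VariantAnnotation", {
  anc <- rbind(make_site("G", pos = 10, G_fwd = 10, G_rev = 10),
               make_site("C", pos = 20, C_fwd = 10, C_rev = 10),
               make_site("G", pos = 30, G_fwd = 10, G_rev = 10))
  evo <- rbind(make_alt_site("G", "T", 20, 20, alt_fwd = 10, pos = 10),
               make_alt_site("C", "A", 2, 20, alt_fwd = 1, pos = 20),
               make_site("G", pos = 30, G_fwd = 10, G_rev = 10))
  res <- call_genome(anc, evo, fp, strain = "S1")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(res, path, emit_all = TRUE, sample_name = "S1")
  back <- read_vcf_calls(path, pass_only = FALSE)
  expect_equal(nrow(back), 2)            # pass + rejected candidate
  expect_equal(back$pos[back$filter == "PASS"], 10L)
  expect_equal(back$filter[back$pos == 20], "LOW_EVOLVED_FRAC")

  skip_if_not_installed("VariantAnnotation")
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  expect_equal(unname(BiocGenerics::start(vcf)), c(10L, 20L))
  expect_equal(as.character(VariantAnnotation::ref(vcf)), c("G", "C"))
})
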