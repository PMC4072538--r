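# --- simulator --------------------------------------------------------------

test_that("noise-free pileups contain only reference matches", {
  g <- generate_annotated_genome(2000, 0, 3)
  pu <- simulate_pileup(g, pileup_sim_params(mean_depth = 10, error_rate = 0,
                                             seed = 2))
  expect_true(all(grepl("^[.,]+$", pu$bases)))
})

test_that("per-site depth follows the Poisson mean", {
  g <- generate_annotated_genome(10000, 0, 3)
  mu <- 50
  pu <- simulate_pileup(g, pileup_sim_params(mean_depth = mu, seed = 7))
  # sites with depth 0 are omitted; at mu = 50 none are expected
  expect_equal(nrow(pu), 10000)
  se <- sqrt(mu / 10000)
  expect_lt(abs(mean(pu$depth) - mu), 3 * se)
})

test_that("a planted variant shows alt fraction 1 under zero noise", {
  g <- generate_annotated_genome(1000, 0, 3)
  strain <- strsplit(g$seq, "")[[1]]
  pos <- 500L
  strain[pos] <- setdiff(c("A", "C", "G", "T"), strain[pos])[1]
  pu <- simulate_pileup(g, pileup_sim_params(mean_depth = 30, error_rate = 0,
                                             seed = 3),
                        strain_seq = paste0(strain, collapse = ""))
  row <- pu[pu$pos == pos, ]
  expect_false(grepl("[.,]", row$bases))
  expect_equal(nchar(row$bases), row$depth)
})

test_that("an empty genome yields an empty pileup stream", {
  empty <- structure(list(seq = "", chrom = "chr",
                          genes = data.frame(gene_id = character(0),
                                             strand = character(0),
                                             start = integer(0),
                                             end = integer(0))),
                     class = "ancestral_genome")
  pu <- simulate_pileup(empty, pileup_sim_params(seed = 1))
  expect_equal(nrow(pu), 0)
})

test_that("pileup simulation is seed-deterministic", {
  g <- generate_annotated_genome(2000, 0, 3)
  p <- pileup_sim_params(mean_depth = 15, error_rate = 0.01,
                         ambiguous_rate = 0.01, deletion_rate = 0.01,
                         seed = 11)
  expect_identical(simulate_pileup(g, p), simulate_pileup(g, p))
})

test_that("simulation parameters are validated", {
  expect_error(pileup_sim_params(mean_depth = 0))
  expect_error(pileup_sim_params(error_rate = 1.5))
})

# --- parser -----------------------------------------------------------------

test_that("reference matches are counted by strand symbol", {
  # '.' is a forward-strand match, ',' reverse: 2 forward + 3 reverse here
  p <- parse_base_string(".,.,,", ref = "G", depth = 5)
  expect_equal(p$counts["G", "fwd"], 2L)
  expect_equal(p$counts["G", "rev"], 3L)
  expect_equal(sum(p$counts), 5L)
  expect_equal(p$n_ambiguous + p$n_deletion, 0L)
})

test_that("mismatch letters are counted by case as strand", {
  p <- parse_base_string("..T,t", ref = "G", depth = 5)
  expect_equal(p$counts["T", "fwd"], 1L)
  expect_equal(p$counts["T", "rev"], 1L)
  expect_equal(p$counts["G", "fwd"], 2L)
  expect_equal(p$counts["G", "rev"], 1L)
})

test_that("read markers, deletions and ambiguous calls are handled", {
  p <- parse_base_string("^~.$,*N", ref = "A", depth = 4)
  expect_equal(p$counts["A", "fwd"], 1L)
  expect_equal(p$counts["A", "rev"], 1L)
  expect_equal(p$n_deletion, 1L)
  expect_equal(p$n_ambiguous, 1L)
})

test_that("indel runs are skipped and not counted as base calls", {
  p <- parse_base_string(".+2AC,", ref = "T", depth = 2)
  expect_equal(p$counts["T", "fwd"], 1L)
  expect_equal(p$counts["T", "rev"], 1L)
  p2 <- parse_base_string(".-10AAAAAAAAAA.", ref = "C", depth = 2)
  expect_equal(sum(p2$counts), 2L)
})

test_that("malformed base strings raise errors naming the line", {
  expect_error(parse_base_string("..^", "A", 2, line = 7), "dangling.*line 7")
  expect_error(parse_base_string(".+5AC.", "A", 2, line = 3),
               "indel length mismatch.*line 3")
  expect_error(parse_base_string("..", "A", 3, line = 12),
               "parsed 2 calls but depth is 3.*line 12")
  expect_error(parse_pileup_line("chr\t5\tA\t1", line_no = 2), "fields")
})

test_that("the vectorised file parser agrees with the scalar parser", {
  lines <- c("chr\t1\tG\t5\t.,.,,\tIIIII",
             "chr\t2\tG\t5\t..T,t\tIIIII",
             "chr\t3\tA\t4\t^~.$,*N\tIIII",
             "chr\t4\tT\t2\t.+2AC,\tII",
             "chr\t5\tC\t3\tg,N\tIII")
  fast <- parse_pileup_lines(lines)
  slow <- do.call(rbind, lapply(seq_along(lines), function(i) {
    parse_pileup_line(lines[i], line_no = i)
  }))
  rownames(slow) <- NULL
  expect_equal(fast, slow)
})

test_that("simulated pileups survive a write/parse round trip", {
  g <- generate_annotated_genome(3000, 0, 5)
  strain <- strsplit(g$seq, "")[[1]]
  mut_pos <- c(100L, 2000L)
  strain[mut_pos] <- ifelse(strain[mut_pos] == "A", "G", "A")
  pu <- simulate_pileup(g, pileup_sim_params(mean_depth = 25,
                                             error_rate = 0.01,
                                             ambiguous_rate = 0.005,
                                             deletion_rate = 0.005, seed = 5),
                        strain_seq = paste0(strain, collapse = ""))
  path <- withr::local_tempfile()
  write_pileup(pu, path)
  tb <- read_pileup(path)
  count_cols <- c("A_fwd", "A_rev", "C_fwd", "C_rev", "G_fwd", "G_rev",
                  "T_fwd", "T_rev", "n_ambiguous", "n_deletion")
  expect_equal(rowSums(tb[, count_cols]), as.numeric(tb$depth))
  expect_equal(tb$pos, pu$pos)
  # at the planted sites the dominant base is the strain base
  for (p in mut_pos) {
    row <- tb[tb$pos == p, ]
    tots <- sapply(c("A", "C", "G", "T"), function(b) {
      row[[paste0(b, "_fwd")]] + row[[paste0(b, "_rev")]]
    })
    expect_equal(names(which.max(tots)), strain[p])
  }
})
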