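toy_msa <- aa_msa(c(a = "MK-V", b = "MKAV"))

test_that("model construction follows the match-column and pseudocount rules", {
  # identical ungapped rows, zero pseudocount: indicator emissions
  m <- build_hmm(aa_msa(c(a = "MKV", b = "MKV", c = "MKV")),
                 pseudocount_weight = 0)
  expect_equal(m$M, 3L)
  expect_equal(unname(m$match_emission[1L, "M"]), 1)
  expect_equal(unname(m$match_emission[2L, "K"]), 1)
  expect_equal(sum(m$match_emission > 0), 3L)

  # column 3 of MK-V/MKAV has gap fraction 0.5 -> insert column
  m2 <- build_hmm(toy_msa)
  expect_equal(m2$M, 3L)
  expect_equal(m2$column_map, c(1L, 2L, 4L))

  expect_equal(m2$metadata$inclusion_evalue, 1e-65)
  expect_error(build_hmm(aa_msa(c(a = "M---", b = "---V"))),
               "no match columns")
})

test_that("every probability row of a built model sums to one", {
  msa <- local({
    rows <- vapply(1:8, function(i) {
      r <- strsplit(random_protein(30, seed = 600 + i), "")[[1L]]
      gaps <- impscan:::withr_seed(700 + i, sample(30, 4))
      r[gaps] <- "-"
      paste(r, collapse = "")
    }, character(1))
    aa_msa(stats::setNames(rows, paste0("r", 1:8)))
  })
  m <- build_hmm(msa)
  expect_true(all(abs(rowSums(m$match_emission) - 1) < 1e-9))
  expect_true(all(abs(rowSums(m$insert_emission) - 1) < 1e-9))
  t <- m$transitions
  for (k in 0:m$M) {
    i <- k + 1L
    expect_equal(sum(exp(c(t$MM[i], t$MI[i], t$MD[i])[is.finite(c(t$MM[i], t$MI[i], t$MD[i]))])),
                 1, tolerance = 1e-9)
    expect_equal(sum(exp(c(t$IM[i], t$II[i]))), 1, tolerance = 1e-9)
    if (k >= 1)
      expect_equal(sum(exp(c(t$DM[i], t$DD[i])[is.finite(c(t$DM[i], t$DD[i]))])),
                   1, tolerance = 1e-9)
  }
})

test_that("forward equals brute-force path enumeration on toy models", {
  models <- list(
    build_hmm(toy_msa),
    build_hmm(aa_msa(c(a = "MKVW", b = "MKVW", c = "M-VW"))),
    build_hmm(aa_msa(c(a = "DE", b = "DE")), pseudocount_weight = 0.5),
    build_hmm(aa_msa(c(a = "WKL-", b = "W-LD", c = "WKLD"))))
  seqs <- c("M", "MK", "MKV", "MKAV", "WDEKL")
  for (m in models) {
    for (s in seqs) {
      fast <- phmm_score(m, aa_seq("q", s), "forward")$log_prob
      slow <- brute_forward_logp(m, s)
      expect_equal(fast, slow, tolerance = 1e-9, info = s)
    }
  }
})

test_that("viterbi never exceeds forward and recovers the obvious path", {
  m <- build_hmm(toy_msa)
  for (s in c("MKV", "MKAV", "AMKVWW", "KKK")) {
    f <- phmm_score(m, aa_seq("q", s), "forward")
    v <- phmm_score(m, aa_seq("q", s), "viterbi")
    expect_lte(v$bit_score, f$bit_score + 1e-12)
  }
  v <- phmm_score(m, aa_seq("q", "MKV"), "viterbi")
  expect_equal(v$path$state, c("M", "M", "M"))
  expect_equal(v$path$node, 1:3)
})

test_that("a family consensus outscores shuffled versions of itself", {
  sim <- simulate_family(family_sim_spec("HisN", n = 8, indel_rate = 0,
                                         seed = 1069))
  rows <- vapply(sim$records, `[[`, character(1), "residues")
  m <- build_hmm(aa_msa(stats::setNames(rows, names(sim$records))))
  consensus <- paste(impscan:::AA_STANDARD[apply(m$match_emission, 1L,
                                                 which.max)],
                     collapse = "")
  cons_bits <- phmm_score(m, aa_seq("cons", consensus), "forward")$bit_score
  shuffled_best <- impscan:::withr_seed(1069, max(vapply(1:100, function(i) {
    s <- paste(sample(strsplit(consensus, "")[[1L]]), collapse = "")
    phmm_score(m, aa_seq("shuf", s), "forward")$bit_score
  }, numeric(1))))
  expect_gt(cons_bits, shuffled_best)
})

test_that("E-values behave like expected false-positive counts", {
  m <- build_hmm(toy_msa)
  expect_error(estimate_evalue(m, 1, 100), "calibrat")
  mlong <- build_hmm(aa_msa(stats::setNames(
    rep(random_protein(40, seed = 801), 3), paste0("r", 1:3))))
  mlong <- calibrate_evalues(mlong, length = 40L, n = 400L, seed = 1069)
  # strictly decreasing in score, linear in db size
  s <- seq(-30, 30, by = 5)
  ev <- estimate_evalue(mlong, s, db_size = 1000)
  expect_true(all(diff(ev) < 0))
  expect_equal(estimate_evalue(mlong, 5, 2000),
               2 * estimate_evalue(mlong, 5, 1000))
  # the median random-sequence score has E-value ~ db_size / 2
  meds <- impscan:::withr_seed(42, vapply(1:201, function(i) {
    s <- paste(sample(impscan:::AA_STANDARD, 40, replace = TRUE,
                      prob = mlong$background), collapse = "")
    phmm_score(mlong, aa_seq("r", s), "forward")$bit_score
  }, numeric(1)))
  ev_med <- estimate_evalue(mlong, stats::median(meds), db_size = 200)
  expect_gt(ev_med, 80)
  expect_lt(ev_med, 120)
})

test_that("models survive the text round trip", {
  m <- build_hmm(toy_msa)
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmm(m, f)
  back <- read_hmm(f)
  expect_equal(back$M, m$M)
  for (s in c("MKV", "MKAV", "AMKV")) {
    expect_equal(phmm_score(back, aa_seq("q", s), "forward")$bit_score,
                 phmm_score(m, aa_seq("q", s), "forward")$bit_score,
                 tolerance = 1e-3)
  }
})

test_that("iterative search converges on a single-sequence database", {
  s <- aa_seq("only", random_protein(60, seed = 900))
  res <- suppressWarnings(
    iterative_search(s, list(s), inclusion_evalue = 0.5, max_iter = 3,
                     calib_n = 150))
  expect_true(res$converged)
  expect_equal(res$included[[res$n_iterations]], "only")
})

test_that("iterative search separates two labeled synthetic families", {
  hisn <- simulate_family(family_sim_spec("HisN", n = 8, seed = 1069))
  suhb <- simulate_family(family_sim_spec("SuhB", n = 8, seed = 2069))
  db <- c(hisn$records, suhb$records)
  res <- iterative_search(REFS$HisN, db, inclusion_evalue = 1e-5,
                          max_iter = 5, calib_n = 150)
  expect_true(res$converged)
  expect_equal(res$included[[res$n_iterations]], sort(names(hisn$records)))
  # included sets never shrink across iterations
  for (i in seq_len(res$n_iterations - 1L))
    expect_true(all(res$included[[i]] %in% res$included[[i + 1L]]))
})
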