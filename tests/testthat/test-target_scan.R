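random_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate the site so that guide position i (1-based, 5' end) faces `base`
set_site_base <- function(site, i, base) {
  L <- nchar(site)
  substr(site, L + 1 - i, L + 1 - i) <- base
  site
}

complement1 <- c(A = "T", C = "G", G = "C", T = "A")

test_that("scheme penalties reproduce the stated cost tables", {
  set.seed(81)
  guide <- random_guide(21)
  perfect <- revcomp(guide)
  expect_equal(score_site_scheme_a(guide, perfect), 0)
  expect_equal(score_site_scheme_b(guide, perfect), 0)

  # G:U wobble at guide position 5 (core) -> 0.5 * 2 = 1.0 in scheme A
  guide_g5 <- guide
  substr(guide_g5, 5, 5) <- "G"
  site <- revcomp(guide_g5)
  wob <- set_site_base(site, 5, "T")   # guide G : site T
  expect_equal(score_site_scheme_a(guide_g5, wob), 1.0)

  # mismatch at guide position 20 (outside 2-13) -> 1.0 undoubled
  g20 <- substr(guide, 20, 20)
  mm_base <- setdiff(c("A", "C", "G", "T"),
                     c(complement1[[g20]],
                       if (g20 == "G") "T" else if (g20 == "T") "G"))[1]
  mm <- set_site_base(revcomp(guide), 20, mm_base)
  expect_equal(score_site_scheme_a(guide, mm), 1.0)
  expect_equal(score_site_scheme_b(guide, mm), 1.0)

  # one G:U at position 15 in scheme B -> 0.5, accepted
  guide_g15 <- guide
  substr(guide_g15, 15, 15) <- "G"
  wob15 <- set_site_base(revcomp(guide_g15), 15, "T")
  expect_equal(score_site_scheme_b(guide_g15, wob15), 0.5)

  # two mismatches at guide positions 3 and 5 violate the seed constraint
  bad <- revcomp(guide)
  for (i in c(3, 5)) {
    gi <- substr(guide, i, i)
    nb <- setdiff(c("A", "C", "G", "T"),
                  c(complement1[[gi]], if (gi == "G") "T" else if (gi == "T") "G"))[1]
    bad <- set_site_base(bad, i, nb)
  }
  expect_equal(score_site_scheme_b(guide, bad), Inf)

  # length errors
  expect_error(score_site_scheme_a(guide, substr(perfect, 1, 18)), "length")
  expect_error(score_site_scheme_b(guide, paste0(perfect, "AA")), "bulges|length")
})

test_that("scalar scorers agree with the independent loop oracles", {
  set.seed(82)
  for (rep in 1:40) {
    guide <- random_guide(sample(20:24, 1))
    L <- nchar(guide)
    site <- revcomp(guide)
    # random corruption
    for (j in sample(L, sample(0:4, 1))) {
      substr(site, j, j) <- sample(c("A", "C", "G", "T"), 1)
    }
    expect_equal(score_site_scheme_a(guide, site), oracle_score_a(guide, site))
    expect_equal(score_site_scheme_b(guide, site), oracle_score_b(guide, site))
    # bulged site: insert one base
    k <- sample(2:L, 1)
    bulged <- paste0(substr(site, 1, k - 1), sample(c("A", "C", "G", "T"), 1),
                     substr(site, k, L))
    expect_equal(score_site_scheme_a(guide, bulged),
                 oracle_score_a(guide, bulged))
  }
})

test_that("score monotonicity: corrupting a paired position never lowers a score", {
  set.seed(83)
  for (rep in 1:10) {
    guide <- random_guide(21)
    site <- revcomp(guide)
    s0a <- score_site_scheme_a(guide, site)
    i <- sample(21, 1)
    gi <- substr(guide, i, i)
    mm <- setdiff(c("A", "C", "G", "T"), complement1[[gi]])[1]
    worse <- set_site_base(site, i, mm)
    expect_gte(score_site_scheme_a(guide, worse), s0a)
    expect_gte(score_site_scheme_b(guide, worse),
               score_site_scheme_b(guide, site))
  }
})

test_that("transcript scan equals the full-offset oracle", {
  set.seed(84)
  for (rep in 1:6) {
    guide <- random_guide(sample(20:23, 1))
    tx <- random_dna_test(600)
    # plant one perfect and one slightly corrupted site
    site <- revcomp(guide)
    site2 <- site
    substr(site2, 3, 3) <- sample(c("A", "C", "G", "T"), 1)
    tx <- paste0(substr(tx, 1, 100), site, substr(tx, 101, 400),
                 site2, substr(tx, 401, 600))
    got <- scan_transcripts(stats::setNames(guide, "g1"),
                            c(tx1 = tx))
    want <- oracle_scan(guide, tx)
    key <- function(df) sort(paste(df$start, df$end, round(df$score_a, 6),
                                   ifelse(is.finite(df$score_b),
                                          round(df$score_b, 6), "Inf")))
    expect_identical(key(got), key(want))
    # consensus sites overlap both an A-passing and a B-passing site
    if (any(got$consensus)) {
      expect_true(all(got$pass_a[got$consensus] | got$pass_b[got$consensus]))
    }
  }
})

test_that("perfect planted site yields exactly one consensus site at its interval", {
  set.seed(85)
  guide <- random_guide(21)
  tx <- paste0(random_dna_test(150), revcomp(guide), random_dna_test(150))
  got <- scan_transcripts(stats::setNames(guide, "g1"), c(tx1 = tx),
                          allow_bulge = FALSE)
  cons <- got[got$consensus, ]
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 150L)
  expect_equal(cons$end, 171L)
  expect_equal(cons$score_a, 0)
  expect_equal(cons$score_b, 0)
})

test_that("scrambled guides find no consensus sites in random transcripts", {
  set.seed(86)
  guide <- random_guide(21)
  tx <- random_dna_test(1000)
  got <- scan_transcripts(stats::setNames(guide, "g1"), c(tx1 = tx))
  expect_equal(sum(got$consensus), 0L)
  want <- oracle_scan(guide, tx)
  expect_equal(nrow(got), nrow(want))
})

test_that("consensus is the intersection of per-scheme passing sites", {
  set.seed(87)
  guide <- random_guide(21)
  # site passing scheme A (~3.0 penalty outside core) but failing scheme B's
  # seed rule: two mismatches at guide positions 3 and 5
  site <- revcomp(guide)
  for (i in c(3, 5)) {
    gi <- substr(guide, i, i)
    nb <- setdiff(c("A", "C", "G", "T"),
                  c(complement1[[gi]], if (gi == "G") "T" else if (gi == "T") "G"))[1]
    site <- set_site_base(site, i, nb)
  }
  sa <- score_site_scheme_a(guide, site)
  expect_lte(sa, 4)
  expect_equal(score_site_scheme_b(guide, site), Inf)
  tx <- paste0(random_dna_test(100), site, random_dna_test(100))
  got <- scan_transcripts(stats::setNames(guide, "g1"), c(tx1 = tx))
  planted <- got[got$start == 100L & got$end == 121L, ]
  expect_equal(nrow(planted), 1L)
  expect_false(planted$consensus)
  # every consensus site must overlap both an A-passing and a B-passing site
  for (j in which(got$consensus)) {
    ova <- any(got$pass_a & pmin(got$end, got$end[j]) -
                 pmax(got$start, got$start[j]) > 0)
    ovb <- any(got$pass_b & pmin(got$end, got$end[j]) -
                 pmax(got$start, got$start[j]) > 0)
    expect_true(ova && ovb)
  }
})
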