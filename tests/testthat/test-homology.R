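test_that("a planted toxin copy passes both thresholds with the derived bit score", {
  withr::with_seed(40, {
    toxin <- substr(make_screp(201, n_domains = 1, domain_len = 40)$sequence, 1, 40)
    ref <- dplyr::bind_rows(lapply(1:10, function(i) {
      make_screp(300 + i, n_domains = 1, domain_len = 400,
                 cys_positions = c(2L, 9L, 16L, 21L),
                 accession = paste0("REF", i))
    }))
    ref$sequence[1] <- toxin
    ref$accession[1] <- "TOX"
    search_space <- sum(nchar(ref$sequence))
    query <- tibble::tibble(accession = "Q1",
                            sequence = paste0(strrep("G", 10), toxin,
                                              strrep("G", 10)))
    hits <- homology_screen(query, ref)
    hit <- hits[hits$toxin_id == "TOX", ]
    expect_equal(nrow(hit), 1)
    S <- diag_self_score(toxin, scoring_scheme()$matrix)
    expect_equal(hit$raw_score, S)
    expect_equal(hit$bit_score, (0.267 * S - log(0.041)) / log(2))
    expect_equal(hit$evalue,
                 nchar(query$sequence) * search_space * 2^(-hit$bit_score))
    expect_gt(hit$bit_score, 35)
    expect_lte(hit$evalue, 1e-6)
    expect_true(hit$passes)
    expect_equal(hit$identity_pct, 100)
    expect_equal(hit$gap_openings, 0L)
  })
})

test_that("shuffled queries never pass the screen at the default thresholds", {
  withr::with_seed(41, {
    ref <- dplyr::bind_rows(lapply(1:10, function(i) {
      make_screp(400 + i, n_domains = 1, accession = paste0("REF", i))
    }))
    shuffles <- dplyr::bind_rows(lapply(1:50, function(i) {
      make_decoy(700 + i, "shuffled", accession = paste0("SH", i))
    }))
    hits <- homology_screen(shuffles, ref)
    expect_equal(sum(hits$passes), 0)
  })
})

test_that("threshold gating is exact and jointly applied", {
  withr::with_seed(42, {
    toxin <- make_screp(500, n_domains = 1)
    ref <- toxin
    ref$accession <- "T1"
    query <- toxin
    query$accession <- "Q1"
    base <- homology_screen(query, ref)
    expect_equal(nrow(base), 1)
    inf_bits <- homology_screen(query, ref, bit_cutoff = Inf)
    expect_equal(nrow(inf_bits), 0)
    all_bits <- homology_screen(query, ref, bit_cutoff = 0, evalue_cutoff = Inf,
                                keep_all = TRUE)
    expect_gte(nrow(all_bits), nrow(base))
    # self-hit: identity 100, mirrors rediscovery of known two-domain toxins
    expect_equal(base$identity_pct, 100)
  })
})

test_that("E-values use query length against reference search space", {
  a <- tibble::tibble(accession = "A", sequence = strrep("CWKDE", 10))
  b <- tibble::tibble(accession = "B",
                      sequence = paste0(strrep("CWKDE", 10), strrep("G", 50)))
  ab <- homology_screen(a, b, keep_all = TRUE, bit_cutoff = 0, evalue_cutoff = Inf)
  ba <- homology_screen(b, a, keep_all = TRUE, bit_cutoff = 0, evalue_cutoff = Inf)
  expect_equal(ab$raw_score, ba$raw_score)      # score is symmetric
  expect_equal(ab$evalue / ba$evalue, (50 * 100) / (100 * 50))
  # m and n swap roles: equal here by construction, so make them differ
  c_ <- tibble::tibble(accession = "C", sequence = strrep("CWKDE", 4))
  ac <- homology_screen(a, c_, keep_all = TRUE, bit_cutoff = 0, evalue_cutoff = Inf)
  ca <- homology_screen(c_, a, keep_all = TRUE, bit_cutoff = 0, evalue_cutoff = Inf)
  expect_equal(ac$raw_score, ca$raw_score)
  expect_equal(ac$evalue, ca$evalue)  # m*n product is the same either way
})

test_that("hit ordering is deterministic and empty references error", {
  withr::with_seed(43, {
    ref <- dplyr::bind_rows(lapply(1:5, function(i) {
      make_screp(600 + i, n_domains = 1, accession = paste0("R", i))
    }))
    q <- dplyr::bind_rows(lapply(1:3, function(i) {
      make_screp(600 + i, accession = paste0("Q", i))
    }))
    h1 <- homology_screen(q, ref, keep_all = TRUE, bit_cutoff = 0,
                          evalue_cutoff = Inf)
    h2 <- homology_screen(q, ref, keep_all = TRUE, bit_cutoff = 0,
                          evalue_cutoff = Inf)
    expect_identical(h1, h2)
    expect_equal(h1$screp_id, sort(h1$screp_id))
    expect_error(homology_screen(q, ref[0, ]), "empty reference")
  })
})

test_that("overlap report finds shared accessions and identical sequences", {
  s1 <- strrep("CWKDE", 10)
  s2 <- strrep("ACDKW", 10)
  screps <- tibble::tibble(accession = c("X1", "X2", "X3"),
                           sequence = c(s1, s2, strrep("GSGSA", 10)))
  ref <- tibble::tibble(accession = c("X1", "T2"),
                        sequence = c(s1, s2))
  ov <- overlap_report(screps, ref)
  expect_equal(nrow(ov), 2)
  expect_equal(ov$match_type, c("accession", "sequence"))
  expect_equal(ov$screp_accession[2], "X2")
  expect_equal(ov$reference_accession[2], "T2")
  none <- overlap_report(screps[3, ], ref[2, ])
  expect_equal(nrow(none), 0)
})

test_that("taxonomy overlap counts distinct candidates per taxon", {
  hits <- tibble::tibble(screp_id = c("a", "a", "b", "c"),
                         toxin_id = c("t1", "t2", "t1", "t1"),
                         passes = c(TRUE, TRUE, TRUE, TRUE))
  screp_tax <- tibble::tibble(accession = c("a", "b"),
                              taxon = c("Arachnida", "Arachnida"))
  ref_tax <- tibble::tibble(accession = "t1", taxon = "Arachnida")
  tab <- taxonomy_overlap(hits, screp_tax, ref_tax)
  expect_equal(tab$n_screps[tab$taxon == "Arachnida"], 2)
  expect_equal(tab$n_screps[tab$taxon == "unannotated"], 1)
  expect_true(tab$shared_with_reference[tab$taxon == "Arachnida"])
  expect_false(tab$shared_with_reference[tab$taxon == "unannotated"])
  expect_equal(sum(tab$n_screps), dplyr::n_distinct(hits$screp_id))
  empty <- taxonomy_overlap(hits[0, ], screp_tax, ref_tax)
  expect_equal(nrow(empty), 0)
})

test_that("the packaged synthetic reference set screens cleanly", {
  ref <- read_fasta(system.file("extdata", "synthetic_reference_toxins.fa",
                                package = "screpmine"))
  expect_equal(nrow(ref), 20)
  # a query built from one reference entry rediscovers exactly that entry
  q <- tibble::tibble(accession = "Q", sequence = ref$sequence[7])
  hits <- homology_screen(q, ref)
  expect_true("SYNTOX07" %in% hits$toxin_id)
  top <- hits[which.min(hits$evalue), ]
  expect_equal(top$toxin_id, "SYNTOX07")
  expect_equal(top$identity_pct, 100)
})
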