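kunitz <- function(acc, start, stop, ipr = "IPR002223",
                   desc = "Kunitz domain") {
  tibble::tibble(accession = acc, analysis = "Pfam", signature_id = "PF00014",
                 signature_desc = desc, start = start, stop = stop,
                 interpro_id = ipr, interpro_desc = desc)
}
lectin <- function(acc, start, stop) {
  tibble::tibble(accession = acc, analysis = "Pfam", signature_id = "PF00139",
                 signature_desc = "Lectin", start = start, stop = stop,
                 interpro_id = "IPR001220", interpro_desc = "Lectin")
}

test_that("two same-type units classify as a pure [AA] repeat", {
  seq <- strrep("ACDKW", 40)  # 200 aa
  ann <- dplyr::bind_rows(kunitz("p", 5, 58), kunitz("p", 70, 120))
  arch <- build_architecture(seq, ann, accession = "p")
  expect_equal(arch$domain_string, "[AA]")
  expect_equal(arch$repeat_class, "pure")
  expect_equal(arch$n_units, 2L)
  # linker length is irrelevant to the classification
  far <- build_architecture(seq, dplyr::bind_rows(kunitz("p", 1, 40),
                                                  kunitz("p", 150, 190)),
                            accession = "p")
  expect_equal(far$repeat_class, "pure")
})

test_that("letters follow first appearance; mixed repeats are combinatorial", {
  seq <- strrep("ACDKW", 40)
  ann <- dplyr::bind_rows(lectin("p", 1, 40), kunitz("p", 50, 100),
                          kunitz("p", 110, 160))
  arch <- build_architecture(seq, ann, accession = "p")
  expect_equal(arch$domain_string, "[ABB]")
  expect_equal(arch$repeat_class, "combinatorial")
  expect_equal(arch$units$letter, c("A", "B", "B"))
  # same content, lectin last: letters reassigned by first appearance
  ann2 <- dplyr::bind_rows(kunitz("p", 1, 50), kunitz("p", 60, 110),
                           lectin("p", 120, 160))
  expect_equal(build_architecture(seq, ann2)$domain_string, "[AAB]")
})

test_that("single or no annotations are non-repeats", {
  seq <- strrep("ACDKW", 30)
  one <- build_architecture(seq, kunitz("p", 5, 58))
  expect_equal(one$domain_string, "[A]")
  expect_equal(one$repeat_class, "non_repeat")
  none <- build_architecture(seq, kunitz(character(0), integer(0), integer(0)))
  expect_equal(none$domain_string, "[]")
  expect_equal(none$repeat_class, "non_repeat")
  expect_equal(none$n_units, 0L)
})

test_that("overlapping same-type annotations merge above 50% overlap", {
  seq <- strrep("ACDKW", 40)
  ann <- dplyr::bind_rows(kunitz("p", 10, 60), kunitz("p", 20, 70),
                          kunitz("p", 100, 150))
  arch <- build_architecture(seq, ann)
  expect_equal(arch$n_units, 2L)
  expect_equal(arch$units$start, c(10L, 100L))
  expect_equal(arch$units$stop, c(70L, 150L))
  # across types the earlier-listed annotation wins
  mixed <- dplyr::bind_rows(kunitz("p", 10, 60), lectin("p", 15, 55))
  expect_equal(build_architecture(seq, mixed)$domain_string, "[A]")
})

test_that("repeat purity is 100 for identical units and symmetric otherwise", {
  unit <- "ACDEFGHIKLMNPQRSTVWY"
  seq2 <- paste0(unit, "GGGGG", unit)
  ann2 <- dplyr::bind_rows(kunitz("p", 1, 20), kunitz("p", 26, 45))
  expect_equal(repeat_purity(build_architecture(seq2, ann2)), 100)

  seq3 <- paste0(unit, unit, unit)
  ann3 <- dplyr::bind_rows(kunitz("p", 1, 20), kunitz("p", 21, 40),
                           kunitz("p", 41, 60))
  expect_equal(repeat_purity(build_architecture(seq3, ann3)), 100)
})

test_that("purity equals the hand-counted identity of a constructed pair", {
  u1 <- "CWKDECWKDE"
  u2 <- "CWGGGCWGGG"  # positions 3-5 and 8-10 substituted
  seqp <- paste0(u1, u2)
  ann <- dplyr::bind_rows(kunitz("p", 1, 10), kunitz("p", 11, 20))
  arch <- build_architecture(seqp, ann)
  # gapless global alignment: 4 identical columns of 10
  g <- global_align(u1, u2)
  expect_equal(g$aln_length, 10L)
  expect_equal(repeat_purity(arch), g$identity_pct)
  expect_equal(repeat_purity(arch), 40)
})

test_that("purity is unit-order invariant and uses the most-copied type", {
  unit <- "ACDEFGHIKLMNPQRSTVWY"
  seq <- paste0(unit, unit, strrep("W", 20))
  # Kunitz repeated twice, lectin once: purity over the Kunitz units
  ann <- dplyr::bind_rows(lectin("p", 41, 60), kunitz("p", 1, 20),
                          kunitz("p", 21, 40))
  expect_equal(repeat_purity(build_architecture(seq, ann)), 100)
  expect_error(repeat_purity(build_architecture(seq, kunitz("p", 1, 20))),
               "purity undefined")
})

test_that("domain frequency reports protein counts and mean copies", {
  seq <- strrep("ACDKW", 40)
  recs <- tibble::tibble(accession = c("p1", "p2", "p3"),
                         sequence = rep(seq, 3))
  # unit coordinates phased so repeated units are byte-identical substrings
  ann <- dplyr::bind_rows(
    kunitz("p1", 1, 50), kunitz("p1", 51, 100),
    kunitz("p2", 1, 50), kunitz("p2", 51, 100),
    lectin("p3", 1, 40), kunitz("p3", 41, 90), kunitz("p3", 91, 140))
  archs <- suppressMessages(build_architectures(recs, ann))
  rep_ <- domain_frequency_report(archs)
  expect_equal(rep_$n_proteins[rep_$domain_type == "IPR002223"], 3)
  expect_equal(rep_$mean_copies_per_protein[rep_$domain_type == "IPR002223"], 2)
  expect_equal(rep_$n_proteins[rep_$domain_type == "IPR001220"], 1)
  expect_equal(rep_$mean_copies_per_protein[rep_$domain_type == "IPR001220"], 1)
  expect_true(all(rep_$mean_copies_per_protein >= 1))
  expect_equal(rep_$domain_type[1], "IPR002223")  # sorted by n_proteins
  # per-protein table agrees
  td <- tidy(archs)
  expect_equal(td$repeat_class, c("pure", "pure", "combinatorial"))
  expect_equal(td$purity_pct, c(100, 100, 100))
})

test_that("domain strings round-trip to the letter sequence", {
  seq <- strrep("ACDKW", 40)
  ann <- dplyr::bind_rows(lectin("p", 1, 40), kunitz("p", 50, 100),
                          kunitz("p", 110, 160))
  arch <- build_architecture(seq, ann)
  parsed <- strsplit(gsub("\\[|\\]", "", arch$domain_string), "")[[1]]
  expect_equal(parsed, arch$units$letter)
  # each letter maps to exactly one type id
  map <- unique(arch$units[, c("letter", "type_id")])
  expect_equal(anyDuplicated(map$letter), 0)
})
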