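test_that("signed fold change follows the -1/ratio convention on published rows", {
  expect_equal(round(signed_fc(7.25, 8.79), 2), -2.91)   # EZH2, WM vs CTRL
  expect_equal(signed_fc(5, 5), 1)
  # from 2-decimal rounded means the recomputed FC sits within +/-0.05
  expect_lt(abs(signed_fc(8.36, 6.01) - 5.12), 0.05)     # ZNF804A prints 5.12
  # antisymmetry and round-trip magnitude
  set.seed(1)
  a <- runif(50, 2, 12); b <- runif(50, 2, 12)
  expect_equal(signed_fc(a, b), -signed_fc(b, a))
  expect_equal(abs(signed_fc(a, b)), 2^abs(a - b))
  expect_true(all(abs(signed_fc(a, b)) >= 1))
  expect_equal(sign(signed_fc(a, b)), sign(a - b))
})

test_that("pattern assignment reproduces the published labels and tie-breaks", {
  expect_equal(assign_pattern(6.49, 7.72, 8.83), "p2")   # IKZF2
  expect_equal(assign_pattern(1.92, 1.75, 3.46), "p3")   # GREB1
  expect_equal(assign_pattern(3.01, 4.05, 4.03), "p4")   # NRG3
  expect_equal(assign_pattern(8.36, 6.01, 5.12), "p1")   # ZNF804A
  # zero second step inherits the first step's sign (PPARGC1A stays p2)
  expect_equal(assign_pattern(3.32, 4.49, 4.49), "p2")
  expect_equal(assign_pattern(5, 5, 5), "flat")
  # non-flat genes land in exactly one pattern
  set.seed(2)
  m <- matrix(runif(300, 3, 10), ncol = 3)
  lab <- assign_pattern(m[, 1], m[, 2], m[, 3])
  expect_true(all(lab %in% c("p1", "p2", "p3", "p4")))
})

test_that("fold-change-sign pattern labels match the printed CD138+ table", {
  cd138 <- published_deg_tables()$cd138
  lab <- pattern_from_fc(cd138$fc_WM_MGUS, cd138$fc_MGUS_CTRL)
  expect_identical(lab, cd138$pattern)
  counts <- table(factor(lab, c("p1", "p2", "p3", "p4")))
  expect_identical(as.vector(counts), c(0L, 26L, 1L, 2L))
})

test_that("the progression filter recovers the nine-gene signature", {
  recs <- published_cd19_records()
  expect_equal(nrow(recs), 15)
  sig <- progression_filter(recs, alpha = 0.05)
  expect_setequal(sig$genes, c("HIST1H1B", "EZH2", "CHEK1", "LEF1", "ADAM23",
                               "RASGRP3", "ADRB2", "PIK3AP1", "CDHR3"))
  rejected <- setdiff(recs$gene, sig$genes)
  expect_setequal(rejected, c("ZNF804A", "ZNF215", "IKZF2", "ADARB1",
                              "ADAM28", "APBB2"))
  # a gene significant in all three comparisons fails the first clause
  allsig <- data.frame(gene = "x", p_WM_MGUS = 0.001, p_MGUS_CTRL = 0.001,
                       p_WM_CTRL = 0.001)
  expect_length(progression_filter(allsig)$genes, 0)
  # missing p-values are skipped with a warning
  nap <- data.frame(gene = c("x", "y"), p_WM_MGUS = c(NA, 0.5),
                    p_MGUS_CTRL = c(0.01, 0.01), p_WM_CTRL = c(0.01, 0.01))
  expect_warning(out <- progression_filter(nap), "x")
  expect_identical(out$genes, "y")
})

test_that("the filter agrees with a clause-by-clause brute force on random tables", {
  set.seed(8)
  tab <- data.frame(gene = paste0("g", 1:200),
                    p_WM_MGUS = runif(200), p_MGUS_CTRL = runif(200),
                    p_WM_CTRL = runif(200))
  sel <- progression_filter(tab, alpha = 0.1)$genes
  brute <- character(0)
  for (i in 1:200) {
    if (tab$p_WM_MGUS[i] >= 0.1 && tab$p_MGUS_CTRL[i] < 0.1 &&
        tab$p_WM_CTRL[i] < 0.1) {
      brute <- c(brute, tab$gene[i])
    }
  }
  expect_identical(sel, brute)
})

test_that("cross-cell-type join carries both patterns and survives disjoint inputs", {
  tabs <- published_deg_tables()
  # CD19-side records reconstructed from the common table's CD19 columns
  cd19 <- data.frame(gene = tabs$common$gene, pattern = tabs$common$pattern_cd19,
                     fc_WM_MGUS = tabs$common$fc_WM_MGUS_cd19,
                     fc_MGUS_CTRL = tabs$common$fc_MGUS_CTRL_cd19,
                     fc_WM_CTRL = tabs$common$fc_WM_CTRL_cd19)
  joined <- cross_celltype_common(cd19, tabs$cd138[!duplicated(tabs$cd138$gene), ])
  expect_setequal(joined$gene,
                  c("TJP1", "GBA3", "NFIB", "PPARGC1A", "MYLK", "SYNM",
                    "ARHGAP32", "MARC2", "LAPTM4B", "PLA2G2D", "KIAA1804"))
  tjp1 <- joined[joined$gene == "TJP1", ]
  expect_equal(tjp1$pattern_cd19, "p4")
  expect_equal(tjp1$pattern_cd138, "p2")
  disjoint <- cross_celltype_common(cd19[0, ], tabs$cd138)
  expect_equal(nrow(disjoint), 0)
})
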