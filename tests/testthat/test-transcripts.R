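test_that("FPKM to TPM rescales to one million", {
  expect_equal(tpm_from_fpkm(c(1, 3, 6)), c(1e5, 3e5, 6e5))
  expect_equal(tpm_from_fpkm(c(0, 7)), c(0, 1e6))
  expect_equal(tpm_from_fpkm(rep(2, 4)), rep(250000, 4))
  for (i in 1:10) {
    set.seed(i)
    v <- rexp(50)
    expect_equal(sum(tpm_from_fpkm(v)), 1e6)
  }
  expect_error(tpm_from_fpkm(c(0, 0)), "zero")
  expect_error(tpm_from_fpkm(c(-1, 2)), "non-negative")
})

test_that("the per-cell content correction is elementwise and tagged", {
  expect_equal(as.numeric(apply_percell_correction(c(100, 0), 0.34)), c(34, 0))
  expect_equal(as.numeric(apply_percell_correction(c(5, 7), 1)), c(5, 7))
  v <- c(3, 1, 4)
  p <- c(2, 3, 1)
  expect_equal(as.numeric(apply_percell_correction(v, 0.34)[p]),
               as.numeric(apply_percell_correction(v[p], 0.34)))
  expect_equal(attr(apply_percell_correction(1, 0.34), "unit"),
               "per-cell-corrected TPM")
  expect_error(apply_percell_correction(1:3, 0), "positive")
})

test_that("the detection threshold is the median of one-zero genes", {
  # genes (low, high): (0,4), (2,0), (1,3), (0,0) -> non-zeros {4, 2} -> 3
  expect_equal(detection_threshold(c(0, 2, 1, 0), c(4, 0, 3, 0)), 3)
  expect_error(detection_threshold(c(1, 2), c(3, 4)), "undefined")
  expect_error(detection_threshold(1:3, 1:2), "equal length")
  # mid-point convention for even counts
  expect_equal(detection_threshold(c(0, 0, 1), c(2, 6, 5)), 4)
})

test_that("flooring discards doubly-undetected genes and floors the rest", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    low = c(5, 0, 0, 0.002),
                    high = c(7, 5, 0, 0.003))
  out <- floor_at_threshold(tab, 0.01)
  expect_equal(out$gene_id, c("a", "b"))
  expect_equal(out$low, c(5, 0.01))
  expect_equal(out$high, c(7, 5))
  # all values above the threshold: identity
  expect_equal(floor_at_threshold(tab[1, ], 0.01), tab[1, ])
})

test_that("fold changes are reported against the genome band", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                    low = c(1, 2, 4), high = c(2, 2, 1))
  fc <- foldchange_vs_genome(tab, c("g1", "g3"))
  expect_equal(fc$genes$log2_fc, c(1, -2))
  expect_equal(fc$genome_mean, mean(c(1, 0, -2)))
  expect_equal(fc$genome_sd, sd(c(1, 0, -2)))
  # identical genes: zero-width band
  tab2 <- data.frame(gene_id = c("a", "b"), low = c(2, 2), high = c(4, 4))
  expect_equal(foldchange_vs_genome(tab2, "a")$genome_sd, 0)
  expect_error(foldchange_vs_genome(tab, "nope"), "missing")
})

test_that("the pipeline order is fixed: TPM, correct, threshold, floor, FC", {
  fpkm_low <- c(10, 0, 1, 0, 50)
  fpkm_high <- c(20, 4, 0, 0, 40)
  low <- apply_percell_correction(tpm_from_fpkm(fpkm_low), 0.34)
  high <- tpm_from_fpkm(fpkm_high)
  tau <- detection_threshold(low, high)
  tab <- data.frame(gene_id = paste0("g", 1:5), low = as.numeric(low),
                    high = high)
  fl <- floor_at_threshold(tab, tau)
  fc <- foldchange_vs_genome(fl, fl$gene_id)

  # frozen regression values, hand-derived from the rule chain:
  # TPM low = (163934.4, 0, 16393.4, 0, 819672.1) * 0.34
  # TPM high = (312500, 62500, 0, 0, 625000)
  # one-zero genes: g2 (0, 62500), g3 (5573.77, 0) -> tau = median = 34036.89
  expect_equal(tau, (62500 + 16393.44262 * 0.34) / 2, tolerance = 1e-8)
  expect_equal(fl$gene_id, c("g1", "g2", "g5"))  # g3, g4 below tau in both
  expect_equal(fl$low[2], tau)   # g2 floored in 'low'
  expect_equal(fc$genes$log2_fc[1],
               log2(312500 / (163934.4262 * 0.34)), tolerance = 1e-6)

  # permuting flooring and correction changes the result
  alt_low <- apply_percell_correction(
    pmax(tpm_from_fpkm(fpkm_low), tau), 0.34)
  expect_false(isTRUE(all.equal(as.numeric(alt_low),
                                pmax(as.numeric(low), tau))))
})
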