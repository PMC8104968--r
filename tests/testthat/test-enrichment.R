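# Fisher/hypergeometric enrichment and promoter-window motif tests.

test_that("Fisher exact p matches hypergeometric enumeration", {
  b <- fisher_or(matrix(c(10, 10, 10, 10), 2))
  expect_equal(b$or, 1)
  expect_equal(b$p, 1)
  d <- fisher_or(matrix(c(5, 0, 0, 5), 2))
  expect_equal(d$p, 2 / choose(10, 5), tolerance = 1e-12)
  set.seed(121)
  for (i in 1:30) {
    m <- matrix(rpois(4, sample(c(2, 5, 15), 1)), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_or(m)$p, fisher_enum_p(m), tolerance = 1e-10)
  }
  dg <- fisher_or(matrix(c(0, 0, 3, 5), 2))
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)
})

test_that("zero cells get the Haldane-Anscombe correction", {
  f <- fisher_or(matrix(c(8, 0, 1, 9), 2))
  expect_true(is.finite(f$log2_or) && is.finite(f$ci[1]) &&
                is.finite(f$ci[2]))
  expect_gt(f$or, 1)
})

test_that("a planted term ranks first in GO enrichment", {
  background <- paste0("g", 1:1000)
  term_map <- list(planted = paste0("g", 1:5),
                   small = paste0("g", 1:2),
                   decoy = paste0("g", 300:340))
  res <- go_enrichment(query = paste0("g", 1:5), background, term_map)
  expect_equal(res$term[1], "planted")
  expect_lt(res$p[1], 1e-10)
  # term of size 2 excluded before correction regardless of overlap
  expect_false("small" %in% res$term)
  # adjusted p never below raw p, capped at 1
  expect_true(all(res$p_adj >= res$p - 1e-15))
  expect_true(all(res$p_adj <= 1))
})

test_that("GO enrichment controls family-wise error under the null", {
  set.seed(122)
  background <- paste0("g", 1:400)
  term_map <- lapply(1:25, function(i) sample(background, 20))
  names(term_map) <- paste0("t", 1:25)
  n_sig <- sapply(1:60, function(i) {
    q <- sample(background, 30)
    sum(go_enrichment(q, background, term_map)$significant)
  })
  expect_lte(mean(n_sig > 0), 0.1)
})

test_that("enrichment results ignore input ordering", {
  set.seed(123)
  background <- paste0("g", 1:200)
  term_map <- list(a = sample(background, 25), b = sample(background, 30))
  q <- sample(background, 40)
  r1 <- go_enrichment(q, background, term_map)
  r2 <- go_enrichment(sample(q), sample(background),
                      term_map[c("b", "a")])
  expect_equal(r1[order(r1$term), ], r2[order(r2$term), ],
               ignore_attr = TRUE)
})

make_tss <- function(n, spacing = 10000) {
  data.frame(gene = paste0("g", 1:n), chrom = "chr1",
             tss = spacing * (1:n), strand = "+",
             stringsAsFactors = FALSE)
}

test_that("motif window boundary is closed at TSS + window", {
  tss <- make_tss(2)
  open <- data.frame(chrom = "chr1", start = 0L, end = 100000L)
  # one hit exactly at TSS + 2000 of gene 1; none near gene 2
  hits <- list(TF1 = data.frame(chrom = "chr1", start = 12000L,
                                end = 12001L))
  res <- tfbm_enrichment(upregulated = "g1", tested = c("g1", "g2"),
                         tss, open, hits, window = 2000)
  expect_equal(res$n_flagged_up, 1)
  # one basepair further is outside
  hits2 <- list(TF1 = data.frame(chrom = "chr1", start = 12001L,
                                 end = 12002L))
  res2 <- tfbm_enrichment("g1", c("g1", "g2"), tss, open, hits2,
                          window = 2000)
  expect_equal(res2$n_flagged_up, 0)
})

test_that("motif hits must fall in open chromatin to count", {
  tss <- make_tss(2)
  open <- data.frame(chrom = "chr1", start = 30000L, end = 40000L)
  hits <- list(TF1 = data.frame(chrom = "chr1", start = c(10100L, 20100L),
                                end = c(10150L, 20150L)))
  res <- tfbm_enrichment("g1", c("g1", "g2"), tss, open, hits)
  expect_equal(res$n_flagged_up + res$n_flagged_rest, 0)
})

test_that("an extreme motif table is flagged with a finite corrected CI", {
  tss <- make_tss(40)
  open <- data.frame(chrom = "chr1", start = 0L, end = 500000L)
  up <- paste0("g", 1:10)
  hits <- list(TF1 = data.frame(chrom = "chr1",
                                start = tss$tss[1:10], end = tss$tss[1:10] + 1L))
  res <- tfbm_enrichment(up, tss$gene, tss, open, hits)
  expect_true(res$pass[1])
  expect_true(all(is.finite(c(res$ci_lo, res$ci_hi))))
})

test_that("random motif placement passes the 1% threshold rarely", {
  set.seed(124)
  tss <- make_tss(120)
  open <- data.frame(chrom = "chr1", start = 0L, end = 2000000L)
  up <- paste0("g", sample(120, 30))
  n_pass <- sapply(1:40, function(i) {
    pos <- sort(sample.int(1300000, 40))
    hits <- list(TF = data.frame(chrom = "chr1", start = pos,
                                 end = pos + 10L))
    sum(tfbm_enrichment(up, tss$gene, tss, open, hits)$pass)
  })
  expect_lte(mean(n_pass), 0.05)
})

test_that("interval overlaps agree with a brute-force scan", {
  set.seed(125)
  for (rep in 1:5) {
    a <- data.frame(chrom = sample(c("c1", "c2"), 30, TRUE),
                    start = sample.int(1000, 30))
    a$end <- a$start + sample.int(50, 30)
    b <- data.frame(chrom = sample(c("c1", "c2"), 20, TRUE),
                    start = sample.int(1000, 20))
    b$end <- b$start + sample.int(80, 20)
    got <- GenomicRanges::countOverlaps(
      molequeen:::intervals_to_granges(a),
      molequeen:::intervals_to_granges(b)) > 0
    want <- sapply(seq_len(nrow(a)), function(i)
      any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i]))
    expect_identical(unname(got), want)
  }
})

test_that("proximity-only mode detects response elements near the query", {
  tss <- make_tss(60)
  q <- paste0("g", 1:15)
  hits <- data.frame(chrom = "chr1", start = tss$tss[1:15] + 500L,
                     end = tss$tss[1:15] + 520L)
  res <- proximity_enrichment(q, tss$gene, tss, hits, cutoff = 2000)
  expect_equal(res$n_near_query, 15)
  expect_equal(res$n_near_rest, 0)
  expect_lt(res$p, 1e-6)
})

test_that("BED files round trip through the interval reader", {
  df <- data.frame(chrom = c("chr1", "chr2"), start = c(100L, 5000L),
                   end = c(200L, 5100L), name = c("a", "b"),
                   score = c(1L, 2L), strand = c("+", "-"))
  path <- tempfile(fileext = ".bed")
  write.table(df, path, sep = "\t", quote = FALSE, col.names = FALSE,
              row.names = FALSE)
  back <- read_bed(path)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
  expect_equal(back$chrom, df$chrom)
  unlink(path)
})
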