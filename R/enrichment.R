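# Fisher / hypergeometric enrichment: gene-set (GO-style) terms and
# transcription-factor binding motifs in open chromatin near transcription
# start sites. Intervals are 0-based half-open throughout.

#' Fisher's exact test with odds ratio and confidence interval
#'
#' Exact two-sided p (sum of hypergeometric probabilities of tables no more
#' probable than observed, conditioning on the margins); odds ratio taken
#' directly from the table (ad/bc); 95% CI by normal approximation on the
#' log odds ratio with a Haldane-Anscombe +0.5 continuity correction when
#' any cell is zero. Tables with a zero margin are degenerate: p = 1, OR
#' undefined, flagged.
#'
#' @param table 2x2 count matrix (or length-4 vector, row-major).
#' @return list with `or`, `log2_or`, `ci` (on the OR scale), `p`,
#'   `degenerate`.
#' @export
fisher_or <- function(table) {
  m <- matrix(as.numeric(table), 2, 2,
              byrow = !is.matrix(table))
  if (any(m < 0) || sum(m) <= 0) stop_arg("counts must be nonnegative, total positive")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(or = NA_real_, log2_or = NA_real_, ci = c(NA_real_, NA_real_),
                p = 1, degenerate = TRUE))
  p <- fisher.test(m)$p.value
  use <- if (any(m == 0)) m + 0.5 else m
  or <- (use[1, 1] * use[2, 2]) / (use[1, 2] * use[2, 1])
  se_log <- sqrt(sum(1 / use))
  ci <- exp(log(or) + c(-1.96, 1.96) * se_log)
  list(or = or, log2_or = log2(or), ci = ci, p = p, degenerate = FALSE)
}

#' Gene Ontology style gene-set enrichment
#'
#' One-sided hypergeometric test per term, restricted to the background
#' set. Terms with fewer than `min_term` background members or fewer than
#' `min_overlap` query members are excluded before multiple-testing
#' correction; surviving p-values are Bonferroni corrected over the tested
#' terms.
#'
#' @param query query gene IDs (subset of background).
#' @param background background gene IDs.
#' @param term_map named list: term -> gene IDs.
#' @param min_term minimum term size within the background.
#' @param min_overlap minimum query/term intersection.
#' @param alpha significance level on the corrected p.
#' @return data.frame with per-term counts, log2 OR and CI, raw and
#'   Bonferroni p, significance flag; ordered by p.
#' @export
go_enrichment <- function(query, background, term_map, min_term = 3,
                          min_overlap = 3, alpha = 0.05) {
  query <- unique(query)
  background <- unique(background)
  extra <- setdiff(query, background)
  if (length(extra))
    stop_arg("query genes missing from background: ",
             paste(head(extra, 5), collapse = ", "))
  if (!length(query))
    return(data.frame(term = character(), term_size = integer(),
                      overlap = integer(), log2_or = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(), p = numeric(),
                      p_adj = numeric(), significant = logical()))
  nq <- length(query)
  nb <- length(background)
  rows <- lapply(names(term_map), function(tm) {
    genes <- intersect(term_map[[tm]], background)
    k <- length(intersect(genes, query))
    if (length(genes) < min_term || k < min_overlap) return(NULL)
    p <- phyper(k - 1, length(genes), nb - length(genes), nq,
                lower.tail = FALSE)
    tab <- matrix(c(k, length(genes) - k,
                    nq - k, nb - length(genes) - (nq - k)), 2, 2)
    f <- fisher_or(tab)
    data.frame(term = tm, term_size = length(genes), overlap = k,
               log2_or = f$log2_or, ci_lo = log2(f$ci[1]),
               ci_hi = log2(f$ci[2]), p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term = character(), term_size = integer(),
                      overlap = integer(), log2_or = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(), p = numeric(),
                      p_adj = numeric(), significant = logical()))
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p * nrow(out), 1)
  out$significant <- out$p_adj < alpha
  out[order(out$p), ]
}

# Nearest distance from each gene's TSS window to interval sets handled via
# GRanges overlap queries; intervals come in 0-based half-open and are
# converted on use.

#' Transcription-factor binding-motif enrichment near TSSs
#'
#' A gene is flagged for a transcription factor when at least one of the
#' TF's motif hits overlaps an open-chromatin interval (>= 1 bp) and lies
#' within `window` bp of the gene's 5'-most TSS (closed window: a hit at
#' exactly TSS + window counts). Per TF, a 2x2 Fisher test compares flagged
#' status between upregulated genes and the rest of the tested genes;
#' factors with p below `p_threshold` are reported.
#'
#' @param upregulated upregulated gene IDs.
#' @param tested all tested gene IDs (includes `upregulated`).
#' @param tss data.frame with `gene`, `chrom`, `tss` (0-based coordinate),
#'   `strand`.
#' @param open_chromatin interval data.frame (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @param motif_hits named list of interval data.frames, one per TF.
#' @param window bp on either side of the TSS.
#' @param p_threshold reporting threshold on the raw Fisher p.
#' @return data.frame per TF: counts, OR, log2 OR, CI, p, `pass` flag;
#'   all TFs are returned, flagged by `pass`.
#' @export
tfbm_enrichment <- function(upregulated, tested, tss, open_chromatin,
                            motif_hits, window = 2000, p_threshold = 0.01) {
  tested <- unique(tested)
  upregulated <- unique(upregulated)
  absent <- setdiff(tested, tss$gene)
  if (length(absent)) {
    message("tfbm_enrichment: ", length(absent),
            " tested gene(s) absent from the TSS table; excluded")
    tested <- setdiff(tested, absent)
    upregulated <- setdiff(upregulated, absent)
  }
  ti <- match(tested, tss$gene)
  # closed window [tss - window, tss + window] on the 0-based point
  win <- data.frame(chrom = tss$chrom[ti],
                    start = pmax(0, tss$tss[ti] - window),
                    end = tss$tss[ti] + window + 1)
  win_gr <- intervals_to_granges(win)
  open_gr <- intervals_to_granges(open_chromatin)
  is_up <- tested %in% upregulated
  rows <- lapply(names(motif_hits), function(tf) {
    hits <- motif_hits[[tf]]
    hit_gr <- intervals_to_granges(hits)
    in_open <- GenomicRanges::countOverlaps(hit_gr, open_gr) > 0
    flagged_gene <- GenomicRanges::countOverlaps(win_gr,
                                                 hit_gr[in_open]) > 0
    tab <- matrix(c(sum(flagged_gene & is_up), sum(!flagged_gene & is_up),
                    sum(flagged_gene & !is_up), sum(!flagged_gene & !is_up)),
                  2, 2)
    f <- fisher_or(tab)
    data.frame(tf = tf, n_flagged_up = tab[1, 1], n_up = sum(is_up),
               n_flagged_rest = tab[1, 2], n_rest = sum(!is_up),
               or = f$or, log2_or = f$log2_or,
               ci_lo = log2(f$ci[1]), ci_hi = log2(f$ci[2]), p = f$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pass <- !is.na(out$p) & out$p < p_threshold
  out[order(out$p), ]
}

#' Response-element proximity test
#'
#' Proximity-only variant: compares, at a distance cutoff, whether query
#' genes are more likely than the rest of the tested genes to have a motif
#' hit within `cutoff` bp of their TSS (open chromatin not required), using
#' the same Fisher framing.
#'
#' @param query query gene IDs.
#' @param tested all tested gene IDs.
#' @param tss TSS table as in [tfbm_enrichment()].
#' @param hits motif/element interval data.frame.
#' @param cutoff distance cutoff in bp.
#' @return one-row data.frame with counts, OR, log2 OR, CI and p.
#' @export
proximity_enrichment <- function(query, tested, tss, hits, cutoff = 2000) {
  tested <- unique(intersect(tested, tss$gene))
  query <- unique(intersect(query, tested))
  ti <- match(tested, tss$gene)
  win <- data.frame(chrom = tss$chrom[ti],
                    start = pmax(0, tss$tss[ti] - cutoff),
                    end = tss$tss[ti] + cutoff + 1)
  near <- GenomicRanges::countOverlaps(intervals_to_granges(win),
                                       intervals_to_granges(hits)) > 0
  is_q <- tested %in% query
  tab <- matrix(c(sum(near & is_q), sum(!near & is_q),
                  sum(near & !is_q), sum(!near & !is_q)), 2, 2)
  f <- fisher_or(tab)
  data.frame(n_near_query = tab[1, 1], n_query = sum(is_q),
             n_near_rest = tab[1, 2], n_rest = sum(!is_q),
             or = f$or, log2_or = f$log2_or, ci_lo = log2(f$ci[1]),
             ci_hi = log2(f$ci[2]), p = f$p)
}
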