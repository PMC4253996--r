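# Tissue-specificity scoring (Jensen-Shannon), expression-level comparison,
# reproductive/vegetative categorization and neighbor-expression correlation.

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon tissue-specificity score
#'
#' For an expression vector over T tissues, the per-tissue specificity score
#' is `1 - sqrt(JSD(p, e_t))`, where `p` is the vector normalized to sum 1,
#' `e_t` the perfectly tissue-specific unit pattern at tissue t, and `JSD`
#' the Jensen-Shannon divergence with base-2 entropy (so `JSD` lies in
#' `[0, 1]` and every score in `[0, 1]`). The JS score of the transcript is
#' the maximum over tissues; it equals 1 iff expression is confined to one
#' tissue. Scores are scale-invariant and permutation-equivariant in tissues.
#'
#' @param x non-negative expression vector with a positive sum, or a matrix
#'   (transcripts x tissues) of such rows.
#' @return for a vector: list with `scores` (per-tissue), `js_score` (max)
#'   and `tissue` (argmax; first on ties). For a matrix: data.frame with one
#'   row per transcript (id, js_score, tissue) carrying the per-tissue score
#'   matrix in attribute `"scores"`.
#' @export
js_specificity <- function(x) {
  if (is.matrix(x)) {
    sc <- t(apply(x, 1, function(v) js_specificity(v)$scores))
    colnames(sc) <- colnames(x)
    top <- max.col(sc, ties.method = "first")
    out <- data.frame(id = rownames(x),
                      js_score = sc[cbind(seq_len(nrow(sc)), top)],
                      tissue = colnames(x)[top],
                      stringsAsFactors = FALSE)
    attr(out, "scores") <- sc
    return(out)
  }
  if (any(x < 0)) stop("expression must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("all-zero expression vector: specificity undefined")
  p <- x / s
  hp <- entropy2(p)
  # JSD(p, e_t) = H((p + e_t)/2) - H(p)/2 ; H(e_t) = 0
  a <- ifelse(p > 0, -(p / 2) * log2(p / 2), 0)
  S <- sum(a)
  q <- (p + 1) / 2
  hm <- S - a + (-q * log2(q))
  jsd <- pmin(pmax(hm - hp / 2, 0), 1)
  scores <- 1 - sqrt(jsd)
  names(scores) <- names(x)
  t_best <- which.max(scores)
  list(scores = scores, js_score = scores[[t_best]],
       tissue = if (!is.null(names(x))) names(x)[t_best] else t_best)
}

#' Expression-level comparison between transcript sets
#'
#' Each transcript is summarized by one expression value: its maximum FPKM
#' across samples by default (a cross-sample mean would erase
#' tissue-specific transcripts), or the mean with `summary = "mean"`.
#' Reports the per-set median and a two-sample location test between every
#' pair of sets: Wilcoxon rank-sum by default (FPKM is heavy-tailed), or
#' Welch's t-test with `test = "t"`.
#'
#' @param sets named list of transcript id vectors.
#' @param fpkm expression matrix.
#' @param summary `"max"` or `"mean"`.
#' @param test `"wilcox"` or `"t"`.
#' @return list: `medians` (named numeric), `p_values` (matrix of pairwise
#'   p-values), `values` (named list of per-transcript summaries).
#' @export
expression_summary <- function(sets, fpkm, summary = c("max", "mean"),
                               test = c("wilcox", "t")) {
  summary <- match.arg(summary)
  test <- match.arg(test)
  if (any(lengths(sets) == 0)) stop("empty transcript set in 'sets'")
  missing <- setdiff(unlist(sets), rownames(fpkm))
  if (length(missing))
    stop("transcripts absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  fun <- if (summary == "max") max else mean
  values <- lapply(sets, function(ids)
    apply(fpkm[ids, , drop = FALSE], 1, fun))
  medians <- vapply(values, stats::median, numeric(1))
  nm <- names(sets)
  p <- matrix(NA_real_, length(sets), length(sets), dimnames = list(nm, nm))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i < j) {
      pv <- if (test == "wilcox")
        stats::wilcox.test(values[[i]], values[[j]], exact = FALSE)$p.value
      else stats::t.test(values[[i]], values[[j]])$p.value
      p[i, j] <- p[j, i] <- pv
    }
  }
  list(medians = medians, p_values = p, values = values)
}

#' Categorize transcripts by the tissue group of their peak specificity
#'
#' A transcript whose JS score reaches `js_floor` is assigned the group of
#' its argmax-specificity tissue (e.g. "reproductive" or "vegetative");
#' transcripts below the floor are "other". A group literally named
#' `"other"` may be used for tissues outside the two organ classes. The
#' groups must partition the samples of the matrix.
#'
#' @param ids transcript ids to categorize.
#' @param fpkm expression matrix.
#' @param tissue_groups named list of sample-id vectors partitioning
#'   `colnames(fpkm)`.
#' @param js_floor minimum JS score for a non-"other" call (default 0.5).
#' @return data.frame: id, category, tissue (supporting tissue), js_score.
#' @export
categorize <- function(ids, fpkm, tissue_groups, js_floor = 0.5) {
  samples <- unlist(tissue_groups, use.names = FALSE)
  if (anyDuplicated(samples))
    stop("a sample appears in more than one tissue group")
  not_grouped <- setdiff(colnames(fpkm), samples)
  if (length(not_grouped))
    stop("samples not assigned to a tissue group: ",
         paste(not_grouped, collapse = ", "))
  missing <- setdiff(ids, rownames(fpkm))
  if (length(missing))
    stop("transcripts absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  js <- js_specificity(fpkm[ids, , drop = FALSE])
  group_of <- stats::setNames(
    rep(names(tissue_groups), lengths(tissue_groups)), samples)
  category <- ifelse(js$js_score >= js_floor,
                     unname(group_of[js$tissue]), "other")
  data.frame(id = ids, category = category, tissue = js$tissue,
             js_score = js$js_score, stringsAsFactors = FALSE)
}

#' Expression correlation between lincRNAs and their closest coding genes
#'
#' Computes the Spearman correlation between each lincRNA's expression and
#' that of its closest protein-coding gene across shared samples, and
#' reports the mean over pairs. As a positional control, lincRNA spans are
#' re-placed uniformly at random within intergenic space (the complement of
#' coding-gene bodies), closest genes recomputed, and the mean correlation
#' recollected `n_shuffles` times; the control mean and standard deviation
#' calibrate the observed value. Pairs with a constant expression vector
#' have undefined correlation; they are excluded and counted.
#'
#' @param linc transcript set or named `GRanges` spans of lincRNAs.
#' @param coding transcript set or named `GRanges` spans of coding genes.
#' @param fpkm expression matrix covering both.
#' @param seqlengths named integer vector of chromosome lengths.
#' @param n_shuffles number of positional shuffles (default 1000).
#' @param seed integer seed for the shuffles.
#' @return list: `mean_rho`, `n_pairs`, `n_undefined`, `shuffle_mean`,
#'   `shuffle_sd`, `shuffle_means` (vector), `pairs` (data.frame id,
#'   closest_gene, rho).
#' @export
neighbor_correlation <- function(linc, coding, fpkm, seqlengths,
                                 n_shuffles = 1000, seed = 1) {
  lsp <- if (methods::is(linc, "GRangesList")) tx_spans(linc) else linc
  gsp <- if (methods::is(coding, "GRangesList")) tx_spans(coding) else coding
  missing <- setdiff(c(names(lsp), names(gsp)), rownames(fpkm))
  if (length(missing))
    stop("transcripts absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  # full lincRNA x gene correlation matrix once; shuffles just re-index it
  suppressWarnings(
    rho_mat <- stats::cor(t(fpkm[names(lsp), , drop = FALSE]),
                          t(fpkm[names(gsp), , drop = FALSE]),
                          method = "spearman"))
  g_chr <- as.character(GenomicRanges::seqnames(gsp))
  g_s <- GenomicRanges::start(gsp); g_e <- GenomicRanges::end(gsp)
  g_ord <- order(names(gsp))  # lexicographic tie-break
  nearest_for <- function(chr, s, e) {
    vapply(seq_along(chr), function(i) {
      on_chrom <- g_chr == chr[i]
      if (!any(on_chrom)) return(NA_integer_)
      d <- pmax(0L, pmax(g_s - e[i], s[i] - g_e))
      d[!on_chrom] <- NA
      best <- which(d == min(d, na.rm = TRUE))
      best[order(match(best, g_ord))][1]
    }, integer(1))
  }
  nearest_idx <- function(spans) {
    nearest_for(as.character(GenomicRanges::seqnames(spans)),
                GenomicRanges::start(spans), GenomicRanges::end(spans))
  }
  mean_rho_for <- function(idx) {
    r <- rho_mat[cbind(seq_along(idx), idx)]
    r <- r[!is.na(idx)]
    mean(r, na.rm = TRUE)
  }
  obs_idx <- nearest_idx(lsp)
  obs_rho <- rho_mat[cbind(seq_along(obs_idx), obs_idx)]
  pairs <- data.frame(id = names(lsp),
                      closest_gene = names(gsp)[obs_idx],
                      rho = obs_rho, stringsAsFactors = FALSE)
  # intergenic space = complement of coding gene bodies
  gaps <- GenomicRanges::gaps(GenomicRanges::reduce(granges_only(gsp),
                                                    ignore.strand = TRUE))
  gaps <- gaps[as.character(GenomicRanges::strand(gaps)) == "*"]
  gaps <- gaps[as.character(GenomicRanges::seqnames(gaps)) %in%
                 names(seqlengths)]
  gap_end_max <- seqlengths[as.character(GenomicRanges::seqnames(gaps))]
  GenomicRanges::end(gaps) <- pmin(GenomicRanges::end(gaps),
                                   unname(gap_end_max))
  gaps <- gaps[GenomicRanges::width(gaps) > 0]
  widths <- GenomicRanges::width(lsp)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  shuffle_means <- vapply(seq_len(n_shuffles), function(k) {
    pos <- random_placements(widths, gaps)
    mean_rho_for(nearest_idx(pos))
  }, numeric(1))
  list(mean_rho = mean(obs_rho, na.rm = TRUE),
       n_pairs = sum(!is.na(obs_rho)),
       n_undefined = sum(is.na(obs_rho)),
       shuffle_mean = mean(shuffle_means),
       shuffle_sd = stats::sd(shuffle_means),
       shuffle_means = shuffle_means,
       pairs = pairs)
}

random_placements <- function(widths, gaps) {
  # place each feature uniformly among intergenic gaps wide enough for it
  starts <- integer(length(widths))
  chroms <- character(length(widths))
  gw <- GenomicRanges::width(gaps)
  for (i in seq_along(widths)) {
    ok <- which(gw >= widths[i])
    if (!length(ok)) stop("no intergenic gap can hold a feature of width ",
                          widths[i])
    slots <- gw[ok] - widths[i] + 1L
    g <- ok[sample.int(length(ok), 1, prob = slots)]
    starts[i] <- GenomicRanges::start(gaps)[g] +
      sample.int(gw[g] - widths[i] + 1L, 1) - 1L
    chroms[i] <- as.character(GenomicRanges::seqnames(gaps))[g]
  }
  GenomicRanges::GRanges(chroms,
                         IRanges::IRanges(starts, width = widths),
                         strand = "*")
}
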