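# Seeded synthetic-transcriptome generator. Fabricates a toy genome,
# annotation, assembled candidate transcriptome, FPKM matrix, conservation
# track, repeat/sRNA loci, miRNAs with planted decoy sites and mutated FSTs,
# together with a truth table, so that every downstream stage has known
# answers. Every random draw flows through the single seeded RNG stream.

NOISE_ROLES <- c("noise_short", "noise_lowFPKM", "noise_strandless",
                 "noise_single_exon_proximal", "noise_coding_orf")

#' Map a planted noise role to the cascade filter it violates
#' @param role character vector of truth-table roles.
#' @return character vector of filter names.
#' @export
role_filter <- function(role) {
  m <- c(noise_short = "length", noise_lowFPKM = "expression",
         noise_strandless = "strand",
         noise_single_exon_proximal = "proximity",
         noise_coding_orf = "coding")
  unname(m[role])
}

#' Generator configuration
#'
#' Defaults define the reference study conditions: a 2-Mb genome over 2
#' chromosomes; 60 coding genes, 10 TE-related mRNAs, 40 true lincRNAs, 20
#' true lncNATs and 15 noise transcripts per role (each violating exactly
#' one cascade filter); 13 tissues split into a reproductive group
#' (panicle, anther, pistil, seed5DAP, seed10DAP, embryo25DAP,
#' endosperm25DAP), a vegetative group (callus, seedling14DAG, shoot14DAG,
#' leaf20DAG, root14DAG) and one extra tissue (sperm); 2 miRNAs with 3
#' planted decoy sites each; 20 FSTs copied from lincRNA bodies or 1-kb
#' upstream regions at a 2% substitution rate. Intergenic spacing is at
#' least 1500 nt except where a role requires proximity, so the 500-bp
#' filter only fires where intended; planted FPKM for expressed transcripts
#' stays at least twice its threshold to avoid boundary flakiness.
#'
#' @param genome_size,n_chrom toy genome geometry.
#' @param n_coding,n_te,n_linc,n_lncnat,n_noise_per_role planted counts.
#' @param tissue_groups named list of tissue ids; names become categories.
#' @param n_mirna,mirna_len,sites_per_mirna decoy plantings.
#' @param n_fst,fst_mut_rate FST plantings.
#' @param min_spacing minimum intergenic spacing, nt.
#' @param js_floor tissue-specificity floor used for planted categories.
#' @param dominant_share range of the dominant tissue's expression share.
#' @param lnc_au,cds_au target A/U composition of lncRNA vs coding sequence.
#' @param overlap_frac_range lncNAT antisense-overlap fraction range.
#' @return config list for [generate_bundle()].
#' @export
synth_config <- function(genome_size = 2e6, n_chrom = 2,
                         n_coding = 60, n_te = 10, n_linc = 40,
                         n_lncnat = 20, n_noise_per_role = 15,
                         tissue_groups = list(
                           reproductive = c("panicle", "anther", "pistil",
                                            "seed5DAP", "seed10DAP",
                                            "embryo25DAP", "endosperm25DAP"),
                           vegetative = c("callus", "seedling14DAG",
                                          "shoot14DAG", "leaf20DAG",
                                          "root14DAG"),
                           other = "sperm"),
                         n_mirna = 2, mirna_len = 21, sites_per_mirna = 3,
                         n_fst = 20, fst_mut_rate = 0.02,
                         min_spacing = 1500, js_floor = 0.5,
                         dominant_share = c(0.75, 0.9),
                         lnc_au = 0.62, cds_au = 0.46,
                         overlap_frac_range = c(0.03, 0.28)) {
  as.list(environment())
}

rand_seq <- function(n, au = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(au / 2, au / 2, (1 - au) / 2, (1 - au) / 2)),
        collapse = "")
}

# The generator keeps each chromosome as a character vector of single bases:
# slice assignment is cheap there, whereas substr<- on a megabase string
# copies the whole string per write.
rand_base_vec <- function(n, au = 0.5) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(au / 2, au / 2, (1 - au) / 2, (1 - au) / 2))
}

lnc_seq <- function(n, au, max_orf = 80, max_tries = 500) {
  for (i in seq_len(max_tries)) {
    s <- rand_seq(n, au)
    if (longest_orf_codons(s) < max_orf) return(s)
  }
  stop("could not draw an ORF-free sequence of length ", n)
}

coding_seq <- function(total_len, min_codons = 110) {
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  gc_w <- vapply(strsplit(codons, ""), function(x)
    sum(x %in% c("G", "C")) + 0.5, numeric(1))
  u5 <- 30L
  n_codons <- max(min_codons, min(220L, (total_len - u5 - 20L) %/% 3L - 2L))
  cds <- paste0("ATG",
                paste(sample(codons, n_codons - 1L, replace = TRUE,
                             prob = gc_w), collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  u3 <- total_len - u5 - nchar(cds)
  if (u3 < 0) stop("coding transcript too short for ", min_codons, " codons")
  paste0(rand_seq(u5, 0.5), cds, rand_seq(u3, 0.55))
}

split_lengths <- function(total, k, min_w = 40L) {
  total <- as.integer(total)
  if (k == 1) return(total)
  w <- as.vector(stats::rgamma(k, shape = 2))
  w <- as.integer(floor(w / sum(w) * (total - k * min_w))) + as.integer(min_w)
  w[k] <- total - sum(w[-k])
  w
}

exon_quota <- function(n, quota) {
  counts <- rep(seq_along(quota), quota)
  counts <- counts[seq_len(min(n, length(counts)))]
  if (length(counts) < n) counts <- c(counts, rep(1L, n - length(counts)))
  sample(counts)
}

# The in-progress genome lives in an environment (one base-character vector
# per chromosome) so that slice writes stay in place instead of copying a
# megabase vector per write.
write_seg <- function(gen, chrom, start, seq) {
  bases <- strsplit(seq, "")[[1]]
  assign(".idx", start:(start + length(bases) - 1L), gen)
  assign(".val", bases, gen)
  eval(bquote(.(as.name(chrom))[.idx] <- .val), gen)
  invisible(NULL)
}

read_seg <- function(gen, chrom, start, end) {
  paste(get(chrom, gen)[start:end], collapse = "")
}

write_tx_seq <- function(gen, chrom, starts, widths, strand, spliced) {
  # distribute a spliced sequence over exons; for minus-strand transcripts
  # the 5' chunk lands (reverse-complemented) on the rightmost exon
  k <- length(widths)
  order_tx <- if (strand == "-") rev(seq_len(k)) else seq_len(k)
  w_tx <- widths[order_tx]
  offs <- cumsum(c(0L, w_tx[-k]))
  for (j in seq_len(k)) {
    ex <- order_tx[j]
    chunk <- substr(spliced, offs[j] + 1L, offs[j] + w_tx[j])
    if (strand == "-")
      chunk <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(chunk)))
    write_seg(gen, chrom, starts[ex], chunk)
  }
  invisible(NULL)
}

read_tx_seq <- function(gen, chrom, starts, widths, strand) {
  pieces <- vapply(seq_along(starts), function(j)
    read_seg(gen, chrom, starts[j], starts[j] + widths[j] - 1L), character(1))
  s <- paste(pieces, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Generate the synthetic file bundle and truth table
#'
#' Deterministic for a fixed `(config, seed)`. Emits `genome.fa`,
#' `annotation.gtf`, `assembled.gtf`, `fpkm.tsv`, `conservation.bedgraph`,
#' `repeats.bed`, `srna_loci.bed`, `mirnas.fa`, `fsts.fa`, `truth.tsv`,
#' `truth_decoys.tsv` and `truth_fsts.tsv` into `out_dir`, and returns the
#' in-memory objects alongside the paths.
#'
#' @param config from [synth_config()].
#' @param seed integer seed governing all randomness.
#' @param out_dir output directory (created if missing).
#' @return list: `paths`, `truth`, `truth_decoys`, `truth_fsts`,
#'   `candidates`, `annotation`, `genome`, `fpkm`, `track`, `repeats`,
#'   `srna_loci`, `mirnas`, `fsts`, `seqlengths`, `config`, `seed`.
#' @export
generate_bundle <- function(config = synth_config(), seed = 42,
                            out_dir = tempfile("bundle")) {
  cfg <- config
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  chrom_len <- as.integer(cfg$genome_size / cfg$n_chrom)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  gen <- new.env(parent = baseenv())
  for (ch in chroms) assign(ch, rand_base_vec(chrom_len, au = 0.58), gen)
  seqlengths <- stats::setNames(rep(chrom_len, cfg$n_chrom), chroms)

  # ---- feature roster ------------------------------------------------------
  n_host <- cfg$n_lncnat
  n_anchor <- cfg$n_noise_per_role
  if (cfg$n_coding < n_host + n_anchor)
    stop("n_coding must be at least n_lncnat + n_noise_per_role")
  units <- c(rep("coding", cfg$n_coding - n_host - n_anchor),
             rep("coding+lncnat", n_host),
             rep("coding+proximal", n_anchor),
             rep("te", cfg$n_te),
             rep("linc", cfg$n_linc),
             rep("noise_short", cfg$n_noise_per_role),
             rep("noise_lowFPKM", cfg$n_noise_per_role),
             rep("noise_strandless", cfg$n_noise_per_role),
             rep("noise_coding_orf", cfg$n_noise_per_role))
  units <- sample(units)

  # exon-count quotas give a deterministic mean exon count near 2.1
  linc_exons <- exon_quota(cfg$n_linc, c(18, 10, 6, 3, 2, 1))
  lncnat_exons <- exon_quota(cfg$n_lncnat, c(8, 6, 3, 2, 1))
  noise_exons <- list(
    noise_short = exon_quota(cfg$n_noise_per_role, c(8, 7)),
    noise_lowFPKM = exon_quota(cfg$n_noise_per_role, c(7, 5, 2, 1)),
    noise_strandless = exon_quota(cfg$n_noise_per_role, c(7, 5, 2, 1)),
    noise_coding_orf = exon_quota(cfg$n_noise_per_role, c(5, 6, 3, 1)))
  counters <- new.env()
  for (nm in c("linc", "lncnat", names(noise_exons)))
    assign(nm, 0L, envir = counters)
  take <- function(role, pool) {
    i <- get(role, envir = counters) + 1L
    assign(role, i, envir = counters)
    pool[i]
  }

  feats <- list()   # per-feature records
  cursor <- stats::setNames(rep(2000L, cfg$n_chrom), chroms)
  chrom_i <- 0L
  cand_n <- 0L
  gene_n <- 0L
  te_n <- 0L

  lnc_total_len <- function(min_len = 210L, max_len = 2800L) {
    max(min_len, min(max_len, round(stats::rlnorm(1, log(850), 0.5))))
  }

  add_feature <- function(id, role, biotype, chrom, strand, starts, widths) {
    feats[[length(feats) + 1L]] <<- list(
      id = id, role = role, biotype = biotype, chrom = chrom,
      strand = strand, starts = starts, widths = widths)
  }

  place_feature <- function(chrom, start, widths) {
    introns <- if (length(widths) > 1)
      sample(60:250, length(widths) - 1L, replace = TRUE) else integer(0)
    starts <- start + cumsum(c(0L, widths[-length(widths)] + introns))
    starts
  }

  lay_lnc_like <- function(role, chrom, start, n_ex, total, strand,
                           au = cfg$lnc_au) {
    total <- max(total, n_ex * 60L)
    widths <- split_lengths(total, n_ex)
    starts <- place_feature(chrom, start, widths)
    s <- lnc_seq(total, au)
    write_tx_seq(gen, chrom, starts, widths,
                 if (strand == "*") "+" else strand, s)
    cand_n <<- cand_n + 1L
    id <- sprintf("cand_%03d", cand_n)
    add_feature(id, role, "candidate", chrom, strand, starts, widths)
    max(starts + widths - 1L)
  }

  lay_coding <- function(biotype, chrom, start, min_codons = 110L) {
    n_ex <- sample(3:6, 1)
    widths <- sample(150:400, n_ex, replace = TRUE)
    starts <- place_feature(chrom, start, widths)
    strand <- sample(c("+", "-"), 1)
    s <- coding_seq(sum(widths), min_codons)
    write_tx_seq(gen, chrom, starts, widths, strand, s)
    if (biotype == "TE_mRNA") {
      te_n <<- te_n + 1L
      id <- sprintf("TE_%02d", te_n)
    } else {
      gene_n <<- gene_n + 1L
      id <- sprintf("gene_%03d", gene_n)
    }
    role <- if (biotype == "TE_mRNA") "TE_mRNA" else "coding"
    add_feature(id, role, biotype, chrom, strand, starts, widths)
    list(id = id, strand = strand, starts = starts, widths = widths,
         end = max(starts + widths - 1L))
  }

  overlap_fracs <- c()
  for (u in units) {
    chrom_i <- chrom_i + 1L
    chrom <- chroms[(chrom_i %% cfg$n_chrom) + 1L]
    gap <- cfg$min_spacing + sample(0:1500, 1)
    start <- cursor[[chrom]] + gap
    end <- start
    if (u == "coding") {
      end <- lay_coding("known_mRNA", chrom, start)$end
    } else if (u == "te") {
      end <- lay_coding("TE_mRNA", chrom, start)$end
    } else if (u == "linc") {
      n_ex <- take("linc", linc_exons)
      end <- lay_lnc_like("true_lincRNA", chrom, start, n_ex,
                          lnc_total_len(), sample(c("+", "-"), 1))
    } else if (u == "noise_short") {
      n_ex <- take("noise_short", noise_exons$noise_short)
      end <- lay_lnc_like("noise_short", chrom, start, n_ex,
                          sample(120:199, 1), sample(c("+", "-"), 1))
    } else if (u == "noise_lowFPKM") {
      n_ex <- take("noise_lowFPKM", noise_exons$noise_lowFPKM)
      end <- lay_lnc_like("noise_lowFPKM", chrom, start, n_ex,
                          lnc_total_len(), sample(c("+", "-"), 1))
    } else if (u == "noise_strandless") {
      n_ex <- take("noise_strandless", noise_exons$noise_strandless)
      end <- lay_lnc_like("noise_strandless", chrom, start, n_ex,
                          lnc_total_len(), "*")
    } else if (u == "noise_coding_orf") {
      n_ex <- take("noise_coding_orf", noise_exons$noise_coding_orf)
      total <- max(420L, lnc_total_len())
      widths <- split_lengths(total, n_ex, min_w = 60L)
      starts <- place_feature(chrom, start, widths)
      strand <- sample(c("+", "-"), 1)
      s <- coding_seq(total, min_codons = 110L)
      write_tx_seq(gen, chrom, starts, widths, strand, s)
      cand_n <- cand_n + 1L
      add_feature(sprintf("cand_%03d", cand_n), "noise_coding_orf",
                  "candidate", chrom, strand, starts, widths)
      end <- max(starts + widths - 1L)
    } else if (u == "coding+proximal") {
      host <- lay_coding("known_mRNA", chrom, start)
      gap2 <- sample(50:450, 1)
      ns <- host$end + gap2 + 1L
      total <- sample(250:900, 1)
      end <- lay_lnc_like("noise_single_exon_proximal", chrom, ns, 1L,
                          total, host$strand)
    } else if (u == "coding+lncnat") {
      host <- lay_coding("known_mRNA", chrom, start, min_codons = 110L)
      n_ex <- take("lncnat", lncnat_exons)
      total <- lnc_total_len(min_len = 300L, max_len = 2200L)
      last_w <- host$widths[length(host$widths)]
      frac <- stats::runif(1, cfg$overlap_frac_range[1],
                           cfg$overlap_frac_range[2])
      ov <- max(8L, round(frac * total))
      ov <- min(ov, last_w - 20L)
      if (n_ex == 1L) {
        widths <- as.integer(total)
      } else {
        w1 <- as.integer(max(ov + 10L, 40L))
        widths <- c(w1, split_lengths(total - w1, n_ex - 1L))
      }
      nat_strand <- if (host$strand == "+") "-" else "+"
      nat_start <- host$end - ov + 1L
      starts <- place_feature(chrom, nat_start, widths)
      # free (non-overlapping) genomic bases get fresh lncRNA-like sequence;
      # the overlapped stretch keeps the host's bases. Base composition is
      # strand-symmetric, so plain forward writes preserve A/U content.
      repeat {
        for (j in seq_along(widths)) {
          a <- starts[j]; b <- starts[j] + widths[j] - 1L
          free_a <- max(a, host$end + 1L)
          if (j == 1L && free_a > a && free_a <= b) {
            write_seg(gen, chrom, free_a, rand_seq(b - free_a + 1L,
                                                   cfg$lnc_au))
          } else if (j > 1L) {
            write_seg(gen, chrom, a, rand_seq(widths[j], cfg$lnc_au))
          }
        }
        spl <- read_tx_seq(gen, chrom, starts, widths, nat_strand)
        if (longest_orf_codons(spl) < 80) break
      }
      cand_n <- cand_n + 1L
      id <- sprintf("cand_%03d", cand_n)
      add_feature(id, "true_lncNAT", "candidate", chrom, nat_strand,
                  starts, widths)
      overlap_fracs[id] <- ov / total
      end <- max(host$end, max(starts + widths - 1L))
    }
    if (end > chrom_len - 3000L)
      stop("synthetic genome too small for the requested feature counts; ",
           "increase genome_size or reduce counts")
    cursor[[chrom]] <- end
  }

  # ---- assemble transcript sets -------------------------------------------
  roles <- vapply(feats, `[[`, character(1), "role")
  ids <- vapply(feats, `[[`, character(1), "id")
  grl <- methods::as(lapply(feats, function(f)
    GenomicRanges::GRanges(f$chrom,
                           IRanges::IRanges(f$starts, width = f$widths),
                           strand = f$strand,
                           seqlengths = seqlengths)), "GRangesList")
  names(grl) <- ids
  biotypes <- vapply(feats, `[[`, character(1), "biotype")
  is_annot <- biotypes %in% c("known_mRNA", "TE_mRNA")
  annotation <- transcript_set(grl[is_annot], gene_id = ids[is_annot],
                               biotype = biotypes[is_annot])
  candidates <- transcript_set(grl[!is_annot], gene_id = ids[!is_annot],
                               biotype = "candidate")
  annotation <- sort_transcripts(annotation)
  candidates <- sort_transcripts(candidates)
  cand_roles <- stats::setNames(roles[!is_annot], ids[!is_annot])

  # ---- miRNAs and planted decoy sites -------------------------------------
  mirnas <- stats::setNames(
    vapply(seq_len(cfg$n_mirna), function(i)
      chartr("T", "U", rand_seq(cfg$mirna_len, au = 0.5)), character(1)),
    sprintf("miR_%02d", seq_len(cfg$n_mirna)))
  site_len <- cfg$mirna_len + 3L
  linc_ids <- ids[roles == "true_lincRNA"]
  first_exon_w <- vapply(feats[match(linc_ids, ids)], function(f) {
    if (f$strand == "-") f$widths[length(f$widths)] else f$widths[1]
  }, integer(1))
  eligible <- linc_ids[first_exon_w >= site_len + 24L]
  n_sites <- cfg$n_mirna * cfg$sites_per_mirna
  if (length(eligible) < n_sites)
    stop("not enough lincRNAs with a long first exon to plant decoy sites")
  decoy_hosts <- sample(eligible, n_sites)
  truth_decoys <- NULL
  for (k in seq_len(n_sites)) {
    mi <- names(mirnas)[ceiling(k / cfg$sites_per_mirna)]
    host_id <- decoy_hosts[k]
    f <- feats[[match(host_id, ids)]]
    mirc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(chartr("U", "T", mirnas[[mi]]))))
    m <- cfg$mirna_len
    fe <- if (f$strand == "-") length(f$widths) else 1L
    w1 <- f$widths[fe]
    q <- sample(10:(w1 - site_len - 10L), 1)
    gstart <- if (f$strand == "-")
      (f$starts[fe] + f$widths[fe] - 1L) - (q + site_len - 1L) + 1L
    else f$starts[fe] + q - 1L
    saved <- read_seg(gen, f$chrom, gstart, gstart + site_len - 1L)
    repeat {
      g <- sample(9:11, 1)
      bulge <- rand_seq(3, 0.5)
      site <- paste0(substr(mirc, 1, m - g), bulge,
                     substr(mirc, m - g + 1, m))
      gseq <- if (f$strand == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
      else site
      write_seg(gen, f$chrom, gstart, gseq)
      spl <- read_tx_seq(gen, f$chrom, f$starts, f$widths, f$strand)
      if (longest_orf_codons(spl) < 100) break
      write_seg(gen, f$chrom, gstart, saved)  # undo and redraw
    }
    truth_decoys <- rbind(truth_decoys, data.frame(
      lncrna_id = host_id, mirna_id = mi, start = q,
      end = q + site_len - 1L, bulge_after = g, stringsAsFactors = FALSE))
  }
  truth_decoys <- truth_decoys[order(truth_decoys$lncrna_id,
                                     truth_decoys$mirna_id,
                                     truth_decoys$start), ]

  # ---- expression matrix ---------------------------------------------------
  tissues <- unlist(cfg$tissue_groups, use.names = FALSE)
  group_of <- stats::setNames(rep(names(cfg$tissue_groups),
                                  lengths(cfg$tissue_groups)), tissues)
  nT <- length(tissues)
  all_ids <- c(names(annotation), names(candidates))
  fpkm <- matrix(0, length(all_ids), nT,
                 dimnames = list(all_ids, tissues))
  # dominant-tissue sampling weights: anther-heavy, mirroring strong male
  # reproductive enrichment
  w <- stats::setNames(rep(0, nT), tissues)
  w["anther"] <- 0.35
  w[setdiff(cfg$tissue_groups$reproductive, "anther")] <- 0.05
  w[cfg$tissue_groups$vegetative] <- 0.04
  w[cfg$tissue_groups$other] <- 0.03
  dominant_tissue <- stats::setNames(rep(NA_character_, length(all_ids)),
                                     all_ids)
  planted_js <- stats::setNames(rep(NA_real_, length(all_ids)), all_ids)

  broad_row <- function(base) {
    round(base * stats::rlnorm(nT, 0, 0.25), 4)
  }
  specific_row <- function(single_exon) {
    repeat {
      t_dom <- sample(tissues, 1, prob = w)
      d <- stats::runif(1, cfg$dominant_share[1], cfg$dominant_share[2])
      M <- max(if (single_exon) 5 else 2.5,
               stats::rlnorm(1, log(15), 0.4))
      rest <- stats::rgamma(nT - 1L, shape = 0.6)
      v <- stats::setNames(rep(0, nT), tissues)
      v[t_dom] <- M
      v[setdiff(tissues, t_dom)] <- (1 - d) / d * M * rest / sum(rest)
      v <- round(v, 4)
      js <- js_specificity(v)
      if (js$js_score >= cfg$js_floor + 0.05 && js$tissue == t_dom)
        return(list(v = v, tissue = t_dom, js = js$js_score))
    }
  }
  uniform_row <- function(single_exon) {
    repeat {
      base <- max(if (single_exon) 5 else 2.5, stats::rlnorm(1, log(8), 0.3))
      v <- base * stats::rlnorm(nT, 0, 0.15)
      thr <- if (single_exon) 2 else 0.5
      if (max(v) < 2 * thr) v <- v * (2 * thr / max(v))
      v <- round(v, 4)
      names(v) <- tissues
      js <- js_specificity(v)
      if (js$js_score <= cfg$js_floor - 0.05)
        return(list(v = v, js = js$js_score))
    }
  }

  n_ex_by_id <- stats::setNames(c(tx_n_exons(annotation),
                                  tx_n_exons(candidates)),
                                c(names(annotation), names(candidates)))
  for (id in all_ids) {
    role <- if (id %in% names(cand_roles)) cand_roles[[id]] else
      if (startsWith(id, "TE_")) "TE_mRNA" else "coding"
    single <- n_ex_by_id[[id]] == 1L
    if (role == "coding") {
      fpkm[id, ] <- broad_row(stats::rlnorm(1, log(19), 0.5))
    } else if (role == "TE_mRNA") {
      fpkm[id, ] <- broad_row(stats::rlnorm(1, log(4.2), 0.5))
    } else if (role == "noise_lowFPKM") {
      fpkm[id, ] <- round(stats::runif(nT, 0.02, 0.2), 4)
    } else {
      uniform <- stats::runif(1) < 0.12
      if (uniform) {
        r <- uniform_row(single)
        fpkm[id, ] <- r$v
        planted_js[id] <- r$js
      } else {
        r <- specific_row(single)
        fpkm[id, ] <- r$v
        dominant_tissue[id] <- r$tissue
        planted_js[id] <- r$js
      }
    }
  }
  planted_category <- stats::setNames(
    ifelse(is.na(dominant_tissue), "other",
           unname(group_of[dominant_tissue])), all_ids)

  # ---- conservation track --------------------------------------------------
  track_v <- lapply(chroms, function(ch) rep(NA_real_, chrom_len))
  names(track_v) <- chroms
  put_scores <- function(chrom, a, b, lo, hi) {
    # piecewise-constant blocks of 10-30 bases around a per-region level,
    # the run structure a conservation track actually has
    n <- b - a + 1L
    base <- stats::runif(1, lo, hi)
    bl <- sample(10:30, ceiling(n / 10) + 1L, replace = TRUE)  # sum >= n
    v <- rep(pmin(1, pmax(0, base + stats::rnorm(length(bl), 0, 0.03))), bl)[
      seq_len(n)]
    track_v[[chrom]][a:b] <<- round(v, 3)
  }
  for (f in feats) {
    kind <- f$role
    for (j in seq_along(f$starts)) {
      a <- f$starts[j]; b <- a + f$widths[j] - 1L
      if (kind %in% c("coding", "TE_mRNA")) {
        put_scores(f$chrom, a, b, 0.55, 0.9)
      } else if (stats::runif(1) < 0.5) {
        put_scores(f$chrom, a, b, 0.05, 0.35)
      }
    }
    if (kind == "coding" && stats::runif(1) < 0.5) {
      a <- f$starts[1]
      track_v[[f$chrom]][a:(a + 19L)] <- round(stats::runif(20, 0.85, 0.98), 3)
    }
  }
  for (i in seq_len(30)) {   # sparse intergenic alignment blocks
    ch <- sample(chroms, 1)
    a <- sample(seq(1000L, chrom_len - 1000L), 1)
    b <- a + sample(200:800, 1)
    seg <- track_v[[ch]][a:b]
    seg[is.na(seg)] <- round(stats::runif(sum(is.na(seg)), 0.02, 0.3), 3)
    track_v[[ch]][a:b] <- seg
  }
  track <- cons_track(track_v)

  # ---- repeats and sRNA loci ----------------------------------------------
  rep_list <- list()
  for (f in feats[roles == "TE_mRNA"]) {
    a <- f$starts[1]; b <- max(f$starts + f$widths - 1L)
    rep_list[[length(rep_list) + 1L]] <-
      GenomicRanges::GRanges(f$chrom, IRanges::IRanges(a - 20L, b + 20L))
  }
  linc_feats <- feats[roles == "true_lincRNA"]
  for (f in linc_feats[1:2]) {   # a small minority of lincRNAs touch repeats
    a <- f$starts[1]
    rep_list[[length(rep_list) + 1L]] <-
      GenomicRanges::GRanges(f$chrom, IRanges::IRanges(a, a + 60L))
  }
  for (i in seq_len(8)) {
    ch <- sample(chroms, 1)
    a <- sample(seq(500L, chrom_len - 2000L), 1)
    rep_list[[length(rep_list) + 1L]] <-
      GenomicRanges::GRanges(ch, IRanges::IRanges(a, a + sample(100:600, 1)))
  }
  repeats <- sort(suppressWarnings(do.call(c, rep_list)),
                  ignore.strand = TRUE)

  srna_list <- list()
  srna_hosts <- c(linc_feats[3:5], feats[roles == "true_lncNAT"][1])
  for (f in srna_hosts) {
    a <- f$starts[1]
    srna_list[[length(srna_list) + 1L]] <-
      GenomicRanges::GRanges(f$chrom, IRanges::IRanges(a + 5L, a + 35L),
                             strand = f$strand)
  }
  for (i in seq_len(8)) {
    ch <- sample(chroms, 1)
    a <- sample(seq(500L, chrom_len - 2000L), 1)
    srna_list[[length(srna_list) + 1L]] <-
      GenomicRanges::GRanges(ch, IRanges::IRanges(a, a + 24L), strand = "*")
  }
  srna_loci <- sort(suppressWarnings(do.call(c, srna_list)),
                    ignore.strand = TRUE)

  # ---- FSTs ----------------------------------------------------------------
  db_names <- c("affjp", "cirad", "gsnu", "ostid", "pfg", "rmd", "ship",
                "trim", "ucd")
  linc_spans <- lapply(linc_feats, function(f)
    c(f$starts[1], max(f$starts + f$widths - 1L)))
  truth_fsts <- NULL
  fst_seqs <- character(0)
  fst_desc <- character(0)
  mutate_seq <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::rbinom(length(ch), 1, rate) == 1)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  for (k in seq_len(cfg$n_fst)) {
    region <- if (k %% 2 == 0) "upstream" else "internal"
    repeat {
      fi <- sample(seq_along(linc_feats), 1)
      f <- linc_feats[[fi]]
      span <- linc_spans[[fi]]
      len <- sample(250:450, 1)
      if (region == "internal") {
        if (span[2] - span[1] + 1L < len + 10L) next
        a <- sample(span[1]:(span[2] - len + 1L), 1)
      } else {
        if (f$strand == "+") {
          up <- c(span[1] - 1000L, span[1] - 1L)
        } else {
          up <- c(span[2] + 1L, span[2] + 1000L)
        }
        a <- sample(up[1]:(up[2] - len + 1L), 1)
      }
      break
    }
    raw <- read_seg(gen, f$chrom, a, a + len - 1L)
    mut <- mutate_seq(raw, cfg$fst_mut_rate)
    if (stats::runif(1) < 0.5)
      mut <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(mut)))
    id <- sprintf("fst_%03d", k)
    db <- sample(db_names, 1)
    fst_seqs[id] <- mut
    fst_desc[id] <- sprintf("%s db=%s", id, db)
    truth_fsts <- rbind(truth_fsts, data.frame(
      mutant_id = id, database = db, lincrna_id = f$id, region = region,
      genomic_start = a, genomic_end = a + len - 1L,
      stringsAsFactors = FALSE))
  }
  fsts <- Biostrings::DNAStringSet(fst_seqs)
  names(fsts) <- names(fst_seqs)
  S4Vectors::mcols(fsts)$database <- truth_fsts$database

  # ---- truth table ---------------------------------------------------------
  cand_ids_sorted <- names(candidates)
  truth <- data.frame(
    transcript_id = cand_ids_sorted,
    role = unname(cand_roles[cand_ids_sorted]),
    planted_class = ifelse(cand_roles[cand_ids_sorted] == "true_lincRNA",
                           "lincRNA",
                           ifelse(cand_roles[cand_ids_sorted] == "true_lncNAT",
                                  "lncNAT", NA_character_)),
    planted_category = ifelse(
      cand_roles[cand_ids_sorted] %in% c("true_lincRNA", "true_lncNAT"),
      planted_category[cand_ids_sorted], NA_character_),
    dominant_tissue = unname(dominant_tissue[cand_ids_sorted]),
    planted_js = unname(planted_js[cand_ids_sorted]),
    overlap_fraction = unname(overlap_fracs[cand_ids_sorted]),
    length = tx_lengths(candidates),
    n_exons = tx_n_exons(candidates),
    stringsAsFactors = FALSE)

  # ---- write the bundle ----------------------------------------------------
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    paste(get(ch, gen), collapse = ""), character(1)))
  names(genome) <- chroms
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    annotation = file.path(out_dir, "annotation.gtf"),
    assembled = file.path(out_dir, "assembled.gtf"),
    fpkm = file.path(out_dir, "fpkm.tsv"),
    conservation = file.path(out_dir, "conservation.bedgraph"),
    repeats = file.path(out_dir, "repeats.bed"),
    srna_loci = file.path(out_dir, "srna_loci.bed"),
    mirnas = file.path(out_dir, "mirnas.fa"),
    fsts = file.path(out_dir, "fsts.fa"),
    truth = file.path(out_dir, "truth.tsv"),
    truth_decoys = file.path(out_dir, "truth_decoys.tsv"),
    truth_fsts = file.path(out_dir, "truth_fsts.tsv"))
  write_fasta(genome, paths$genome)
  write_gtf(annotation, paths$annotation)
  write_gtf(candidates, paths$assembled)
  write_expression(fpkm, paths$fpkm)
  write_bedgraph(track, paths$conservation)
  write_bed(repeats, paths$repeats)
  write_bed(srna_loci, paths$srna_loci)
  mir_set <- Biostrings::RNAStringSet(mirnas)
  Biostrings::writeXStringSet(mir_set, paths$mirnas)
  fst_out <- fsts
  names(fst_out) <- unname(fst_desc[names(fsts)])
  Biostrings::writeXStringSet(fst_out, paths$fsts)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth_decoys, paths$truth_decoys, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth_fsts, paths$truth_fsts, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(paths = paths, truth = truth, truth_decoys = truth_decoys,
       truth_fsts = truth_fsts, candidates = candidates,
       annotation = annotation, genome = genome, fpkm = fpkm, track = track,
       repeats = repeats, srna_loci = srna_loci,
       mirnas = Biostrings::RNAStringSet(mirnas), fsts = fsts,
       seqlengths = seqlengths, config = cfg, seed = seed)
}
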