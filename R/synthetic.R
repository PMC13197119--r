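# Seeded generator of a miniature multi-TF, multi-cell world with planted
# binding structure: binding probability is driven by accessibility x motif
# affinity x expression (+ a planted cooperating TF pair), with ~2% positive
# prevalence and ~5% ambiguous labels, mirroring the data classes of the
# real pipeline at CI scale.

#' Synthetic-world configuration
#'
#' Defaults describe the stated world: 2,000 regions of 350 bp on 3 training
#' chromosomes plus 1 held-out test chromosome, 5 TFs, 4 cell types, target
#' positive prevalence 2\% and 5\% ambiguous labels. Signal weights put
#' accessibility first and motif second (matching the observed feature
#' importance ordering), expression and cooperation as weaker drivers.
#'
#' @param n_regions number of regions.
#' @param n_tfs number of TFs (>= 2).
#' @param n_cells number of cell types (>= 2).
#' @param n_chromosomes number of training chromosomes.
#' @param n_test_chromosomes held-out chromosomes appended after the
#'   training ones.
#' @param region_length region width in bp (<= 350).
#' @param prevalence target positive fraction, in (0, 0.5).
#' @param ambiguous_frac fraction of (region, TF, cell) triples relabeled
#'   ambiguous at random.
#' @param w_atac,w_motif,w_expr,w_coop signal weights on the binding logit.
#' @param noise_sd sd of the logit noise.
#' @param shared_frac shared-vs-TF-specific effect mix in [0, 1]; 1 means
#'   all TFs share the same effect sizes (maximum transfer benefit).
#' @param motif_implant_prob probability a TF's consensus site is implanted
#'   in a region's sequence.
#' @param motif_length implanted motif length.
#' @param n_controls number of control sequences for affinity p-scores.
#' @param embedding_dim columns of the optional sequence-embedding matrix.
#' @param coop_n,coop_k enhancer-selection sizes for the cooperation module,
#'   scaled to the fixture (the full-scale analysis uses 5000/1000).
#' @param seed mandatory integer seed; generation is a pure function of the
#'   config.
#' @return a list of class \code{tfb_synth_config}.
#' @export
synthetic_config <- function(n_regions = 2000L, n_tfs = 5L, n_cells = 4L,
                             n_chromosomes = 3L, n_test_chromosomes = 1L,
                             region_length = 350L,
                             prevalence = 0.02, ambiguous_frac = 0.05,
                             w_atac = 1.5, w_motif = 1.0, w_expr = 0.5,
                             w_coop = 0.5, noise_sd = 1,
                             shared_frac = 0.7,
                             motif_implant_prob = 0.15, motif_length = 8L,
                             n_controls = 100L, embedding_dim = 16L,
                             coop_n = NULL, coop_k = NULL,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(prevalence > 0, prevalence < 0.5,
            w_atac >= 0, w_motif >= 0, w_expr >= 0, w_coop >= 0,
            shared_frac >= 0, shared_frac <= 1,
            n_tfs >= 2, n_cells >= 2, region_length <= 350)
  # cooperation set sizes scale with the fixture (full-scale: 5000 / 1000)
  if (is.null(coop_n))
    coop_n <- min(200L, as.integer(floor(n_regions / (1 + n_cells))))
  if (is.null(coop_k))
    coop_k <- max(5L, as.integer(floor(coop_n / 5)))
  if (coop_n > n_regions / (1 + n_cells))
    stop("coop_n infeasible for this world size")
  if (coop_k > coop_n)
    stop("coop_k infeasible: must be <= coop_n")
  structure(as.list(environment()), class = "tfb_synth_config")
}

rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste0(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
}

implant_site <- function(seq, site) {
  len <- nchar(seq); sl <- nchar(site)
  off <- sample.int(len - sl + 1L, 1L)
  paste0(substr(seq, 1, off - 1L), site, substr(seq, off + sl, len))
}

zscore <- function(x) (x - mean(x)) / max(sd(as.vector(x)), 1e-8)

#' Generate a synthetic world
#'
#' Produces regions with chromosome assignments, sequences with implanted
#' consensus motif sites, per-TF PWMs, per-(region, cell) ATAC and
#' footprint values, per-(TF, cell) TPM, region x cell enhancer
#' probabilities, optional sequence embeddings, and ternary labels sampled
#' from the planted binding logit
#' \deqn{w_{atac} z(\log atac) + w_{motif} z(maxPWM) + w_{expr} 1[TPM>0] +
#'   w_{coop} coop + \epsilon,}
#' with the intercept calibrated so the positive fraction matches the target
#' prevalence. Latent generative quantities are retained for recovery tests.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return a list of class \code{tfb_world}.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "tfb_synth_config"))
  set.seed(config$seed)
  n <- config$n_regions
  tfs <- paste0("TF", seq_len(config$n_tfs))
  cells <- paste0("cell", seq_len(config$n_cells))
  chroms_train <- paste0("chr", seq_len(config$n_chromosomes))
  chroms_test <- paste0("chr",
                        config$n_chromosomes + seq_len(config$n_test_chromosomes))
  chroms <- c(chroms_train, chroms_test)

  chrom_of <- sample(chroms, n, replace = TRUE)
  idx_in_chrom <- stats::ave(seq_len(n), chrom_of, FUN = seq_along)
  start <- (idx_in_chrom - 1L) * 500L
  regions <- region_set(chrom_of, start, start + config$region_length,
                        region_id = sprintf("r%05d", seq_len(n)),
                        max_length = config$region_length)

  # PWMs: strong consensus motifs, one per TF
  pwms <- lapply(tfs, function(tf) {
    cons <- sample(4, config$motif_length, replace = TRUE)
    probs <- matrix(0.05, nrow = config$motif_length, ncol = 4)
    probs[cbind(seq_len(config$motif_length), cons)] <- 0.85
    pwm_matrix(tf, probs)
  })
  names(pwms) <- tfs

  # sequences with implanted consensus sites
  seqs <- rand_seq(n, config$region_length)
  implanted <- matrix(runif(n * config$n_tfs) < config$motif_implant_prob,
                      nrow = n, dimnames = list(regions$region_id, tfs))
  for (t in seq_along(tfs)) {
    cons <- pwm_consensus(pwms[[t]])
    hit <- which(implanted[, t])
    for (i in hit) seqs[i] <- implant_site(seqs[i], cons)
  }
  names(seqs) <- regions$region_id
  controls <- rand_seq(config$n_controls, config$region_length)

  # motif scan of the generated sequences (the features downstream see)
  scan <- scan_region_motifs(seqs, pwms, controls = controls)
  max_pwm <- matrix(0, nrow = n, ncol = config$n_tfs,
                    dimnames = list(regions$region_id, tfs))
  n_sites <- aff_p <- total_aff <- max_pwm
  idx <- cbind(match(scan$region_id, regions$region_id),
               match(scan$tf, tfs))
  max_pwm[idx] <- scan$max_score
  n_sites[idx] <- scan$n_sites
  total_aff[idx] <- scan$total_affinity
  aff_p[idx] <- scan$affinity_pscore

  # accessibility: shared region openness x cell-specific variation
  base_open <- rnorm(n, 0, 0.6)
  atac <- exp(outer(base_open, rep(0, config$n_cells), "+") +
              matrix(rnorm(n * config$n_cells, 0, 0.6), nrow = n))
  dimnames(atac) <- list(regions$region_id, cells)

  # footprinting: accessibility modulated by motif content ("hybrid feature")
  motif_summary <- zscore(rowMeans(max_pwm))
  footprint <- atac * matrix(stats::plogis(motif_summary),
                             nrow = n, ncol = config$n_cells) +
    matrix(abs(rnorm(n * config$n_cells, 0, 0.1)), nrow = n)
  dimnames(footprint) <- dimnames(atac)

  # cell-type-agnostic genomic tracks
  remap <- setNames(exp(rnorm(n, 0, 0.5)), regions$region_id)
  phastcons <- setNames(runif(n), regions$region_id)

  # expression: each TF expressed in ~70% of cells
  expressed <- matrix(runif(config$n_tfs * config$n_cells) < 0.7,
                      nrow = config$n_tfs, dimnames = list(tfs, cells))
  tpm <- matrix(0, nrow = config$n_tfs, ncol = config$n_cells,
                dimnames = list(tfs, cells))
  tpm[expressed] <- rlnorm(sum(expressed), log(10), 1)

  # enhancer probabilities track accessibility with noise
  crup <- stats::plogis(zscore(log(atac)) +
                        matrix(rnorm(n * config$n_cells, 0, 0.5), nrow = n))
  dimnames(crup) <- dimnames(atac)

  # planted cooperating pair: TF1-TF2 in the first cell type
  coop_pair <- tfs[1:2]
  coop_cell <- cells[1]
  co_implanted <- implanted[, coop_pair[1]] & implanted[, coop_pair[2]]

  # binding logit with shared-vs-TF-specific effect mix
  tf_mult <- config$shared_frac +
    (1 - config$shared_frac) * runif(config$n_tfs, 0.5, 1.5)
  z_atac <- zscore(log(atac))
  z_motif <- zscore(max_pwm)
  logit <- array(0, dim = c(n, config$n_tfs, config$n_cells),
                 dimnames = list(regions$region_id, tfs, cells))
  for (t in seq_len(config$n_tfs)) {
    for (c in seq_len(config$n_cells)) {
      coop <- if (tfs[t] %in% coop_pair && cells[c] == coop_cell)
        as.numeric(co_implanted) else 0
      logit[, t, c] <- tf_mult[t] *
        (config$w_atac * z_atac[, c] + config$w_motif * z_motif[, t] +
         config$w_expr * as.numeric(expressed[t, c]) + config$w_coop * coop)
    }
  }
  eps <- array(rnorm(length(logit), 0, config$noise_sd), dim = dim(logit))
  logit <- logit + eps

  # intercept calibration to the target prevalence
  f <- function(b) mean(stats::plogis(logit + b)) - config$prevalence
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop("infeasible prevalence calibration")
  intercept <- uniroot(f, c(lo, hi), tol = 1e-10)$root

  prob <- stats::plogis(logit + intercept)
  bound <- array(rbinom(length(prob), 1, prob), dim = dim(prob))
  grid <- expand.grid(region_id = regions$region_id, tf = tfs, cell = cells,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lab <- ifelse(as.vector(bound) == 1L, "B", "U")
  amb <- runif(length(lab)) < config$ambiguous_frac
  lab[amb] <- "A"
  labels <- data.frame(grid, label = lab, stringsAsFactors = FALSE)

  # weakly informative sequence embeddings (random projection of signal)
  sig <- cbind(zscore(rowMeans(z_motif)), zscore(base_open))
  proj <- matrix(rnorm(2 * config$embedding_dim, 0, 0.5),
                 nrow = 2)
  embeddings <- sig %*% proj +
    matrix(rnorm(n * config$embedding_dim), nrow = n)
  dimnames(embeddings) <- list(regions$region_id,
                               paste0("emb", seq_len(config$embedding_dim)))

  structure(list(
    config = config, regions = regions,
    train_chromosomes = chroms_train, test_chromosomes = chroms_test,
    sequences = seqs, controls = controls, pwms = pwms,
    implanted = implanted,
    atac = atac, footprint = footprint, remap = remap,
    phastcons = phastcons, tpm = tpm, expressed = expressed, crup = crup,
    max_pwm = max_pwm, n_sites = n_sites, total_affinity = total_aff,
    affinity_pscore = aff_p,
    embeddings = embeddings, labels = labels,
    latent = list(logit = logit, intercept = intercept, tf_mult = tf_mult,
                  coop_pair = coop_pair, coop_cell = coop_cell,
                  co_implanted = co_implanted)),
    class = "tfb_world")
}

#' @export
print.tfb_world <- function(x, ...) {
  prev <- mean(x$labels$label == "B")
  cat(sprintf("synthetic world: %d regions, %d TFs, %d cells; %.2f%% bound, %.2f%% ambiguous\n",
              nrow(x$regions), ncol(x$max_pwm), ncol(x$atac),
              100 * prev, 100 * mean(x$labels$label == "A")))
  invisible(x)
}

#' Overlapping ground-truth bins consistent with a world's labels
#'
#' Emits DREAM-style labeled bins (six 150-bp bins at 50-bp steps per
#' region) whose aggregation under the harmonization rules reproduces the
#' world's region labels, for end-to-end label-pipeline tests.
#'
#' @param world a \code{tfb_world}.
#' @param pairs optional data.frame (tf, cell) restricting which pairs to
#'   emit (defaults to all).
#' @return data.frame (chrom, start, end, tf, cell, label) of bins.
#' @export
world_bin_labels <- function(world, pairs = NULL) {
  if (is.null(pairs))
    pairs <- unique(world$labels[, c("tf", "cell")])
  out <- list()
  reg <- world$regions
  for (k in seq_len(nrow(pairs))) {
    lab <- merge(reg, world$labels[world$labels$tf == pairs$tf[k] &
                                   world$labels$cell == pairs$cell[k], ],
                 by = "region_id", sort = FALSE)
    for (i in seq_len(nrow(lab))) {
      bl <- switch(lab$label[i],
                   B = c("B", "B", "B", "U", "U", "U"),  # 50% B -> rule 1
                   A = c("B", "U", "U", "U", "U", "U"),  # 1 B, no A -> rule 3
                   U = rep("U", 6))
      out[[length(out) + 1L]] <- data.frame(
        chrom = lab$chrom[i],
        start = lab$start[i] + 0:5 * 50L,
        end = lab$start[i] + 0:5 * 50L + 150L,
        tf = pairs$tf[k], cell = pairs$cell[k], label = bl,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a synthetic world as the file tree the pipeline reads
#'
#' Emits regions.bed, sequences.fa, controls.fa, pwms.transfac, per-cell
#' ATAC/footprint bedGraphs, remap/phastcons bedGraphs, tpm.tsv (long
#' format), crup.tsv, embeddings.tsv, labels.tsv and config.json.
#'
#' @param world a \code{tfb_world}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- world$regions
  write.table(reg[, c("chrom", "start", "end", "region_id")],
              file.path(dir, "regions.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(paste0(">", names(world$sequences), "\n", world$sequences),
             file.path(dir, "sequences.fa"))
  writeLines(paste0(">control", seq_along(world$controls), "\n",
                    world$controls),
             file.path(dir, "controls.fa"))
  write_transfac(world$pwms, file.path(dir, "pwms.transfac"))
  region_track <- function(values) {
    signal_track(reg$chrom, reg$start, reg$end, values)
  }
  for (cell in colnames(world$atac)) {
    write_bedgraph(region_track(world$atac[, cell]),
                   file.path(dir, paste0("atac_", cell, ".bedGraph")))
    write_bedgraph(region_track(world$footprint[, cell]),
                   file.path(dir, paste0("footprint_", cell, ".bedGraph")))
  }
  write_bedgraph(region_track(world$remap), file.path(dir, "remap.bedGraph"))
  write_bedgraph(region_track(world$phastcons),
                 file.path(dir, "phastcons.bedGraph"))
  tpm_long <- data.frame(
    gene = rep(rownames(world$tpm), ncol(world$tpm)),
    condition = rep(colnames(world$tpm), each = nrow(world$tpm)),
    tpm = as.vector(world$tpm), stringsAsFactors = FALSE)
  write.table(tpm_long, file.path(dir, "tpm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix_tsv(world$crup, file.path(dir, "crup.tsv"), key = "region_id")
  write_matrix_tsv(world$embeddings, file.path(dir, "embeddings.tsv"),
                   key = "region_id")
  write_labelset(world$labels, file.path(dir, "labels.tsv"))
  cfg <- unclass(world$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a written world directory back into matrices
#'
#' Inverse of \code{\link{write_world}} for the files the pipeline consumes
#' (latent generative quantities are not persisted).
#'
#' @param dir directory written by \code{\link{write_world}}.
#' @return a list with regions, sequences, controls, pwms, atac, footprint,
#'   remap, phastcons, tpm, crup, embeddings and labels.
#' @export
read_world <- function(dir) {
  regions <- read_regions_bed(file.path(dir, "regions.bed"))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "sequences.fa"))
  seqs <- setNames(as.character(fa), names(fa))
  ctl <- Biostrings::readDNAStringSet(file.path(dir, "controls.fa"))
  # written probabilities already include the pseudocount
  pwms <- read_transfac(file.path(dir, "pwms.transfac"), pseudocount = 0)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cells <- sub("^atac_(.*)\\.bedGraph$", "\\1",
               basename(Sys.glob(file.path(dir, "atac_*.bedGraph"))))
  read_track_values <- function(path) {
    tr <- read_bedgraph(path)
    setNames(tr$value, regions$region_id[
      match(paste(tr$chrom, tr$start), paste(regions$chrom, regions$start))])
  }
  atac <- sapply(cells, function(cell)
    read_track_values(file.path(dir, paste0("atac_", cell, ".bedGraph"))))
  footprint <- sapply(cells, function(cell)
    read_track_values(file.path(dir, paste0("footprint_", cell, ".bedGraph"))))
  atac <- atac[regions$region_id, , drop = FALSE]
  footprint <- footprint[regions$region_id, , drop = FALSE]
  tpm_long <- read.delim(file.path(dir, "tpm.tsv"), stringsAsFactors = FALSE)
  tfs <- unique(tpm_long$gene)
  tpm <- matrix(0, nrow = length(tfs), ncol = length(cells),
                dimnames = list(tfs, cells))
  tpm[cbind(match(tpm_long$gene, tfs), match(tpm_long$condition, cells))] <-
    tpm_long$tpm
  list(config = cfg, regions = regions, sequences = seqs,
       controls = as.character(ctl), pwms = pwms,
       atac = atac, footprint = footprint,
       remap = read_track_values(file.path(dir, "remap.bedGraph")),
       phastcons = read_track_values(file.path(dir, "phastcons.bedGraph")),
       tpm = tpm,
       crup = read_matrix_tsv(file.path(dir, "crup.tsv")),
       embeddings = read_matrix_tsv(file.path(dir, "embeddings.tsv")),
       labels = read_labelset(file.path(dir, "labels.tsv")))
}

#' Load a world directory and recompute its motif-scan matrices
#'
#' Reads the file tree and rescans the sequences with the PWMs so the
#' result is directly consumable by \code{\link{build_features}}.
#'
#' @param dir directory written by \code{\link{write_world}}.
#' @return a list shaped like a \code{tfb_world} (no latent slot).
#' @export
world_from_files <- function(dir) {
  w <- read_world(dir)
  tfs <- names(w$pwms)
  ids <- w$regions$region_id
  scan <- scan_region_motifs(w$sequences, w$pwms, controls = w$controls)
  mk <- function(col) {
    m <- matrix(0, nrow = length(ids), ncol = length(tfs),
                dimnames = list(ids, tfs))
    m[cbind(match(scan$region_id, ids), match(scan$tf, tfs))] <- scan[[col]]
    m
  }
  w$max_pwm <- mk("max_score")
  w$n_sites <- mk("n_sites")
  w$total_affinity <- mk("total_affinity")
  w$affinity_pscore <- mk("affinity_pscore")
  w
}
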