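#' Score called regions against a planted truth set
#'
#' Calls and truth regions are matched greedily by interval Jaccard
#' (overlap / union). A pair matches when its Jaccard reaches
#' \code{match_threshold}; precision is matched calls over all calls,
#' recall matched truths over all truths.
#'
#' @param calls region data.frame (e.g. [call_hgt()] output).
#' @param truth_regions planted region data.frame.
#' @param match_threshold minimum Jaccard for a match (default 0.5).
#' @return list: \code{precision}, \code{recall}, \code{jaccard} (per
#'   matched truth region), \code{n_calls}, \code{n_truth}.
#' @export
evaluate_calls <- function(calls, truth_regions, match_threshold = 0.5) {
  n_calls <- nrow(calls); n_truth <- nrow(truth_regions)
  if (n_truth == 0) stop("empty truth set")
  jac <- matrix(0, n_calls, n_truth)
  for (i in seq_len(n_calls)) for (j in seq_len(n_truth)) {
    if (calls$chrom[i] != truth_regions$chrom[j]) next
    ov <- min(calls$end[i], truth_regions$end[j]) -
      max(calls$start[i], truth_regions$start[j])
    if (ov <= 0) next
    un <- max(calls$end[i], truth_regions$end[j]) -
      min(calls$start[i], truth_regions$start[j])
    jac[i, j] <- ov / un
  }
  matched_truth <- rep(NA_real_, n_truth)
  used <- logical(n_calls)
  for (j in seq_len(n_truth)) {
    if (n_calls == 0) break
    i <- which.max(ifelse(used, -1, jac[, j]))
    if (jac[i, j] >= match_threshold) {
      matched_truth[j] <- jac[i, j]
      used[i] <- TRUE
    }
  }
  list(precision = if (n_calls) sum(used) / n_calls else NA_real_,
       recall = sum(!is.na(matched_truth)) / n_truth,
       jaccard = matched_truth,
       n_calls = n_calls, n_truth = n_truth)
}

#' Simulate a planted dataset, run the caller, and score it
#'
#' The parameter-recovery harness: generates alignment blocks with planted
#' HGT regions under \code{cfg}, calls regions with \code{params}, and
#' scores the calls against the planted truth.
#'
#' @param cfg a [sim_config()].
#' @param params a [call_params()].
#' @return the [evaluate_calls()] report, plus \code{calls} and
#'   \code{truth}.
#' @export
simulate_and_run <- function(cfg, params = call_params()) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  sizes <- setNames(rep(as.integer(cfg$chrom_length), cfg$n_chroms), chroms)
  panel <- sim_panel(cfg)
  sim <- plant_hgt_alignments(cfg, sizes, panel)
  calls <- call_hgt(sim$blocks, panel, params)
  res <- evaluate_calls(calls, sim$truth$regions)
  res$calls <- calls
  res$truth <- sim$truth
  res
}

#' Run configuration for the end-to-end pipeline
#'
#' @param blocks,panel,chrom_sizes paths to the alignment-block, panel and
#'   chrom.sizes tables.
#' @param genome_fasta,genes,chromatin,repeats,histone optional paths to
#'   the focal FASTA and BED annotation tracks.
#' @param out_dir output directory (created if missing).
#' @param params a [call_params()].
#' @param scheme a [window_scheme()].
#' @param end_fraction end-zone fraction for the positional-bias test.
#' @param identity_grid,coverage_grid threshold sensitivity grids.
#' @param seed seed echoed into the manifest (the caller itself is
#'   deterministic).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(blocks, panel, chrom_sizes, out_dir,
                       genome_fasta = NULL, genes = NULL, chromatin = NULL,
                       repeats = NULL, histone = NULL,
                       params = call_params(), scheme = window_scheme(),
                       end_fraction = 0.10,
                       identity_grid = c(0.4, 0.5, 0.6),
                       coverage_grid = c(0.4, 0.2, 0), seed = 1L) {
  cfg <- as.list(environment())
  paths <- c(blocks = blocks, panel = panel, chrom_sizes = chrom_sizes,
             genome_fasta = genome_fasta, genes = genes,
             chromatin = chromatin, repeats = repeats, histone = histone)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop("missing input file(s): ",
         paste(names(missing), unname(missing), sep = "=", collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Run the full analysis over one set of input files
#'
#' Stages: ingest and validate inputs, call HGT regions, compute the
#' threshold sensitivity grid, the chromosome end-bias test, gene and
#' chromatin composition tables, gene overlaps, and windowed GC / repeat /
#' histone profiles for whichever annotation inputs are present. All
#' outputs land in \code{cfg$out_dir} together with a manifest (parameter
#' echo, input checksums) that suffices to reproduce the run; given
#' identical inputs and config the outputs are byte-identical.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress per-stage progress lines.
#' @return invisible list of all computed objects.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[hgtscan] ", ...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- read_species_panel(cfg$panel)
  sizes <- read_chrom_sizes(cfg$chrom_sizes)
  blocks <- read_alignment_blocks(cfg$blocks, panel, sizes)
  say("ingest: ", nrow(blocks), " blocks, ", nrow(panel), " species, ",
      length(sizes), " chromosomes")

  calls <- call_hgt(blocks, panel, cfg$params)
  validate_hgt_calls(calls, cfg$params)
  say("caller: ", nrow(calls), " HGT regions (",
      sum(calls$end - calls$start), " bases)")
  bed <- calls[, c("chrom", "start", "end", "n_nonmammal", "mammal_support")]
  write_regions_bed(bed, file.path(cfg$out_dir, "hgt_regions.bed"))
  jsonlite::write_json(
    list(regions = bed,
         nonmammal_supporters = lapply(calls$nonmammal_supporters, identity),
         mammal_supporters = lapply(calls$mammal_supporters, identity)),
    file.path(cfg$out_dir, "hgt_regions.json"), auto_unbox = FALSE,
    digits = NA)

  grid <- threshold_grid(blocks, panel, cfg$identity_grid,
                         cfg$coverage_grid, cfg$params)
  write.table(grid, file.path(cfg$out_dir, "threshold_grid.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say("grid: ", nrow(grid), " parameter cells")

  out <- list(panel = panel, sizes = sizes, blocks = blocks, calls = calls,
              grid = grid)

  if (nrow(calls) >= 1 && length(sizes) >= 2) {
    eb <- end_bias_test(calls, sizes, cfg$end_fraction)
    jsonlite::write_json(list(t = eb$t, p = eb$p, df = eb$df,
                              per_chrom = eb$per_chrom),
                         file.path(cfg$out_dir, "end_bias.json"),
                         auto_unbox = TRUE, digits = NA)
    say("end bias: t=", signif(eb$t, 4), " p=", signif(eb$p, 4))
    out$end_bias <- eb
  }

  if (!is.null(cfg$genes) && nrow(calls) >= 1) {
    genes <- read_annotation_bed(cfg$genes, "gene")
    comp_g <- composition(calls, genes, sizes, gene_biotype_priority())
    write.table(comp_g, file.path(cfg$out_dir, "composition_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ov <- gene_overlap(calls, genes)
    write.table(ov[, setdiff(names(ov), "regions")],
                file.path(cfg$out_dir, "gene_overlap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("genes: ", attr(ov, "n_genes"), " overlapped")
    out$composition_genes <- comp_g; out$gene_overlap <- ov
  }
  if (!is.null(cfg$chromatin) && nrow(calls) >= 1) {
    chrom_track <- read_annotation_bed(cfg$chromatin, "chromatin")
    comp_c <- composition(calls, chrom_track, sizes,
                          chromatin_state_priority(),
                          default_label = "Heterochrom")
    write.table(comp_c, file.path(cfg$out_dir, "composition_chromatin.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$composition_chromatin <- comp_c
  }

  profiles <- list()
  if (!is.null(cfg$genome_fasta) && nrow(calls) >= 1) {
    genome <- Biostrings::readDNAStringSet(cfg$genome_fasta)
    profiles$GC <- gc_profile(calls, genome, cfg$scheme)
  }
  if (!is.null(cfg$repeats) && nrow(calls) >= 1) {
    rep_track <- read_annotation_bed(cfg$repeats, "repeat")
    for (lab in sort(unique(rep_track$label)))
      profiles[[lab]] <- coverage_profile(calls, rep_track, lab, sizes,
                                          cfg$scheme)
  }
  if (!is.null(cfg$histone) && nrow(calls) >= 1) {
    his_track <- read_annotation_bed(cfg$histone, "histone")
    for (lab in sort(unique(his_track$label)))
      profiles[[lab]] <- coverage_profile(calls, his_track, lab, sizes,
                                          cfg$scheme, signal = TRUE)
  }
  if (length(profiles)) {
    write.table(profile_table(profiles),
                file.path(cfg$out_dir, "window_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("profiles: ", length(profiles), " features")
    out$profiles <- profiles
  }

  inputs <- Filter(Negate(is.null),
                   cfg[c("blocks", "panel", "chrom_sizes", "genome_fasta",
                         "genes", "chromatin", "repeats", "histone")])
  manifest <- list(
    package = "hgtscan",
    version = as.character(utils::packageVersion("hgtscan")),
    seed = cfg$seed,
    params = unclass(cfg$params),
    scheme = unclass(cfg$scheme),
    end_fraction = cfg$end_fraction,
    identity_grid = cfg$identity_grid,
    coverage_grid = cfg$coverage_grid,
    inputs = lapply(inputs, function(p) list(path = p,
                                             md5 = unname(tools::md5sum(p)))),
    n_blocks = nrow(blocks), n_regions = nrow(calls),
    total_bases = sum(calls$end - calls$start))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("manifest written: ", nrow(calls), " called regions")
  invisible(out)
}

#' Write one synthetic dataset to disk in the pipeline's input formats
#'
#' Convenience wrapper used by the analysis scripts: simulates a genome,
#' annotation tracks and planted alignment blocks under \code{cfg} and
#' writes them (FASTA, TSV, BED, truth BED + JSON sidecar) into
#' \code{dir}.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @return named list of written paths (plus the truth object).
#' @export
write_synthetic_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- simulate_genome(cfg)
  panel <- sim_panel(cfg)
  sim <- plant_hgt_alignments(cfg, g$sizes, panel)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(g$genome, p("genome.fa"))
  write_chrom_sizes(g$sizes, p("genome.chrom.sizes"))
  write_species_panel(panel, p("panel.tsv"))
  write_alignment_blocks(sim$blocks, p("blocks.tsv"))
  write_annotation_bed(g$tracks$gene, p("genes.bed"))
  write_annotation_bed(g$tracks$chromatin, p("chromatin.bed"))
  write_annotation_bed(g$tracks$`repeat`, p("repeats.bed"))
  write_annotation_bed(g$tracks$histone, p("histone.bed"))
  write_planted_truth(sim$truth, p("truth.bed"), p("truth.json"))
  list(genome_fasta = p("genome.fa"), chrom_sizes = p("genome.chrom.sizes"),
       panel = p("panel.tsv"), blocks = p("blocks.tsv"),
       genes = p("genes.bed"), chromatin = p("chromatin.bed"),
       repeats = p("repeats.bed"), histone = p("histone.bed"),
       truth_bed = p("truth.bed"), truth_json = p("truth.json"),
       truth = sim$truth)
}
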