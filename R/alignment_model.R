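#' @importFrom IRanges IRanges reduce coverage slice restrict
#' @importFrom S4Vectors runValue runLength
#' @importFrom stats rpois rlnorm rnorm runif sd setNames as.dist pt
#' @importFrom utils read.delim write.table head tail packageVersion
NULL

# All genomic coordinates in this package are 0-based, half-open
# ([start, end), BED convention). Browser-style 1-based inclusive literals
# must be converted on ingest (see from_browser_coords()).

#' Species panel: which species are mammals, which are not
#'
#' A species panel labels every aligned species as \code{mammal} or
#' \code{non_mammal}. The caller requires at least two non-mammals and at
#' least one mammal.
#'
#' @param species character vector of unique species identifiers.
#' @param clade character vector, one of \code{"mammal"}/\code{"non_mammal"}
#'   per species.
#' @return data.frame with columns \code{species}, \code{clade}.
#' @export
species_panel <- function(species, clade) {
  stopifnot(length(species) == length(clade))
  panel <- data.frame(species = as.character(species),
                      clade = as.character(clade),
                      stringsAsFactors = FALSE)
  validate_panel(panel)
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("species", "clade") %in% names(panel)))
  if (anyDuplicated(panel$species))
    stop("duplicated species ids in panel: ",
         paste(unique(panel$species[duplicated(panel$species)]), collapse = ", "))
  bad <- setdiff(unique(panel$clade), c("mammal", "non_mammal"))
  if (length(bad))
    stop("unknown clade label(s): ", paste(bad, collapse = ", "))
  panel[, c("species", "clade")]
}

#' @rdname species_panel
#' @param path path to a two-column TSV with header \code{species},
#'   \code{clade}.
#' @export
read_species_panel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_panel(df)
}

#' @rdname species_panel
#' @param panel a species panel data.frame.
#' @export
write_species_panel <- function(panel, path) {
  write.table(validate_panel(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Chromosome sizes
#'
#' Reads/writes a UCSC-style \code{chrom.sizes} two-column TSV (no header):
#' chromosome name and length in bp.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "length"))
  validate_chrom_sizes(setNames(as.integer(df$length), df$chrom))
}

validate_chrom_sizes <- function(sizes) {
  if (is.null(names(sizes)) || anyDuplicated(names(sizes)))
    stop("chromosome names must be unique and non-missing")
  if (any(sizes <= 0) || anyNA(sizes)) stop("chromosome lengths must be > 0")
  sizes
}

#' @rdname read_chrom_sizes
#' @param sizes named integer vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  validate_chrom_sizes(sizes)
  write.table(data.frame(chrom = names(sizes), length = as.integer(sizes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Genome regions
#'
#' A region table holds 0-based half-open intervals on the focal genome.
#'
#' @param chrom,start,end vectors of equal length.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
genome_regions <- function(chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("regions must satisfy start < end")
  if (any(df$start < 0)) stop("regions must satisfy start >= 0")
  df
}

#' Convert browser-style coordinates to 0-based half-open
#'
#' Genome browsers print 1-based fully-closed coordinates (e.g.
#' \code{chr11:71072901-71074379}); internally everything is 0-based
#' half-open.
#'
#' @param x character vector of \code{chrom:start-end} literals.
#' @return a region data.frame (see [genome_regions()]).
#' @export
from_browser_coords <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))
  if (any(lengths(m) != 4)) stop("malformed coordinate literal")
  num <- function(i) as.integer(gsub(",", "", vapply(m, `[`, "", i)))
  genome_regions(vapply(m, `[`, "", 2), num(3) - 1L, num(4))
}

#' Alignment block tables
#'
#' An alignment block records one aligned interval between the focal genome
#' and one other species, with the fraction of focal bases matched
#' (\code{identity}). Tables are TSV with header
#' \code{species, chrom, start, end, identity}.
#'
#' @param path file path.
#' @param panel species panel used to validate \code{species}.
#' @param sizes optional named chromosome lengths; when given, block ends are
#'   checked against them.
#' @return data.frame with columns \code{species}, \code{chrom},
#'   \code{start}, \code{end}, \code{identity}.
#' @export
read_alignment_blocks <- function(path, panel, sizes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "chrom", "start", "end", "identity")
  if (!all(need %in% names(df)))
    stop("alignment block table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$identity <- as.numeric(df$identity)
  validate_blocks(df, panel, sizes)
}

validate_blocks <- function(blocks, panel = NULL, sizes = NULL) {
  bad_row <- function(i, what)
    stop(sprintf("alignment block row %d (%s %s:%d-%d): %s", i,
                 blocks$species[i], blocks$chrom[i], blocks$start[i],
                 blocks$end[i], what))
  if (!is.null(panel)) {
    panel <- validate_panel(panel)
    unk <- which(!(blocks$species %in% panel$species))
    if (length(unk)) bad_row(unk[1], "species not in panel")
  }
  i <- which(!(blocks$start >= 0 & blocks$start < blocks$end))
  if (length(i)) bad_row(i[1], "requires 0 <= start < end")
  i <- which(!(blocks$identity >= 0 & blocks$identity <= 1))
  if (length(i)) bad_row(i[1], "identity outside [0,1]")
  if (!is.null(sizes)) {
    i <- which(!(blocks$chrom %in% names(sizes)))
    if (length(i)) bad_row(i[1], "unknown chromosome")
    i <- which(blocks$end > sizes[blocks$chrom])
    if (length(i)) bad_row(i[1], "end beyond chromosome length")
  }
  blocks
}

#' @rdname read_alignment_blocks
#' @param blocks a block data.frame.
#' @export
write_alignment_blocks <- function(blocks, path) {
  write.table(blocks[, c("species", "chrom", "start", "end", "identity")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Identity of one gapped alignment row pair
#'
#' Identity is defined relative to the focal genome: the number of columns
#' where both rows carry the same non-gap base, divided by the number of
#' columns where the focal row carries a non-gap base. Gap columns in the
#' focal row therefore do not enter the denominator, which keeps identity and
#' coverage in the same (focal) coordinate system.
#'
#' @param focal_seq,other_seq equal-length strings of one pairwise alignment
#'   (gap character \code{-}).
#' @return fraction in \[0, 1\].
#' @export
block_identity <- function(focal_seq, other_seq) {
  a <- strsplit(toupper(focal_seq), "")[[1]]
  b <- strsplit(toupper(other_seq), "")[[1]]
  if (length(a) != length(b)) stop("alignment rows must have equal length")
  focal_base <- a != "-"
  if (!any(focal_base)) stop("focal row is all gaps")
  sum(focal_base & b != "-" & a == b) / sum(focal_base)
}

#' Annotation tracks
#'
#' Typed genomic intervals: gene biotypes, chromatin states, repeat classes,
#' or histone signal. Files are BED6-compatible (chrom, start, end, label,
#' value, strand), the track type being declared per file.
#'
#' @param chrom,start,end,label interval columns; \code{label} is the class
#'   (biotype, chromatin state, repeat class, histone mark).
#' @param value numeric signal, 1 for presence/absence tracks.
#' @param strand,id optional strand and feature id (genes need unique ids).
#' @param track one of \code{"gene"}, \code{"chromatin"}, \code{"repeat"},
#'   \code{"histone"}.
#' @return data.frame with attribute \code{track}.
#' @export
annotation_track <- function(chrom, start, end, label, value = 1,
                             strand = "+", id = NA_character_,
                             track = c("gene", "chromatin", "repeat", "histone")) {
  track <- match.arg(track)
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), label = as.character(label),
                   value = as.numeric(value), strand = as.character(strand),
                   id = as.character(id), stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("annotation intervals must satisfy start < end")
  if (any(!nzchar(df$label)) || anyNA(df$label)) stop("labels must be non-empty")
  if (any(df$value < 0)) stop("values must be >= 0")
  attr(df, "track") <- track
  df
}

#' @rdname annotation_track
#' @param path BED6 file; column 4 is the label, column 5 the value. For gene
#'   tracks the label may be \code{id|biotype}, splitting into an id and a
#'   biotype label.
#' @export
read_annotation_bed <- function(path, track) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "value", "strand")
  lab <- df$name; id <- NA_character_
  if (track == "gene" && any(grepl("|", lab, fixed = TRUE))) {
    parts <- strsplit(lab, "|", fixed = TRUE)
    id <- vapply(parts, `[`, "", 1)
    lab <- vapply(parts, `[`, "", 2)
  }
  annotation_track(df$chrom, df$start, df$end, lab, df$value, df$strand,
                   id = id, track = track)
}

#' @rdname annotation_track
#' @param ann an annotation track data.frame.
#' @export
write_annotation_bed <- function(ann, path) {
  name <- ann$label
  if (identical(attr(ann, "track"), "gene") && !all(is.na(ann$id)))
    name <- paste(ann$id, ann$label, sep = "|")
  write.table(data.frame(ann$chrom, ann$start, ann$end, name, ann$value,
                         ann$strand),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname genome_regions
#' @param regions region data.frame; written as BED3 (plus optional extra
#'   columns).
#' @param path file path.
#' @export
write_regions_bed <- function(regions, path) {
  write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname genome_regions
#' @export
read_regions_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  genome_regions(df[[1]], df[[2]], df[[3]])
}

# 0-based half-open region/block rows -> IRanges (1-based closed)
as_iranges0 <- function(start, end) IRanges(start = start + 1L, end = end)

# IRanges -> 0-based half-open data.frame
from_iranges0 <- function(chrom, ir) {
  if (length(ir) == 0)
    return(genome_regions(character(), integer(), integer() + 1L)[0, ])
  data.frame(chrom = chrom, start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir), stringsAsFactors = FALSE)
}
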