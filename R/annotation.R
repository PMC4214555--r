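#' Construct an annotation set
#'
#' An `AnnotationSet` holds the located features of one strain's genome:
#' protein-coding genes, RNA genes and candidate RUFs, each with an optional
#' family identifier linking homologs across strains. Coordinates are
#' 0-based half-open throughout the package; conversion to and from the
#' 1-based closed GFF3 convention happens only in [read_annotation()] and
#' [write_annotation()].
#'
#' @param strain_id Strain identifier (single string).
#' @param genome_length Genome length in nucleotides (positive integer).
#' @param features A data frame with columns `feature_id`, `family_id`
#'   (`NA` allowed), `kind` (one of `"protein"`, `"rna"`, `"ruf"`),
#'   `start`, `end` (0-based half-open) and `strand` (`"+"`, `"-"` or
#'   `"both"`). May have zero rows.
#' @return An object of class `AnnotationSet`.
#' @export
annotation_set <- function(strain_id, genome_length, features = empty_features()) {
  stopifnot(is.character(strain_id), length(strain_id) == 1L)
  genome_length <- as.integer(genome_length)
  if (is.na(genome_length) || genome_length <= 0L)
    stop("genome_length must be a positive integer")
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  req <- c("feature_id", "family_id", "kind", "start", "end", "strand")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols))
    stop("features is missing columns: ", paste(missing_cols, collapse = ", "))
  features <- features[req]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features)) {
    if (anyDuplicated(features$feature_id))
      stop("feature_id values must be unique within a strain")
    if (!all(features$kind %in% c("protein", "rna", "ruf")))
      stop("feature kind must be one of 'protein', 'rna', 'ruf'")
    if (!all(features$strand %in% c("+", "-", "both")))
      stop("feature strand must be '+', '-' or 'both'")
    bad <- features$start < 0L | features$start >= features$end |
      features$end > genome_length
    if (any(bad))
      stop("feature interval outside [0, genome_length) or empty: ",
           paste(features$feature_id[bad], collapse = ", "))
  }
  structure(list(strain_id = strain_id, genome_length = genome_length,
                 features = features),
            class = "AnnotationSet")
}

empty_features <- function() {
  data.frame(feature_id = character(), family_id = character(),
             kind = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: strain %s, genome %d nt, %d features (%s)\n",
              x$strain_id, x$genome_length, nrow(x$features),
              paste(sprintf("%s: %d", names(table(x$features$kind)),
                            as.integer(table(x$features$kind))),
                    collapse = ", ")))
  invisible(x)
}

#' Default mapping from GFF3 feature types to internal kinds
#'
#' `CDS` maps to `"protein"`; `ncRNA`, `tRNA`, `rRNA`, `tmRNA` and any
#' other type ending in `RNA` map to `"rna"`; `ncRNA_candidate` (the type
#' this package writes for RUF calls) maps to `"ruf"`. Types not covered
#' by the mapping are skipped with a warning.
#'
#' @return Named character vector mapping GFF3 types to kinds.
#' @export
default_type_map <- function() {
  c(CDS = "protein", gene = "protein",
    ncRNA = "rna", tRNA = "rna", rRNA = "rna", tmRNA = "rna",
    antisense_RNA = "rna", RNase_P_RNA = "rna", SRP_RNA = "rna",
    ncRNA_candidate = "ruf")
}

#' Read a genome annotation from GFF3
#'
#' Parses a GFF3 file into an [annotation_set()]. The genome length is
#' taken from the `##sequence-region` pragma when present, otherwise from
#' the maximum feature end. GFF3 1-based closed coordinates are converted
#' to the internal 0-based half-open convention; GFF3 strand `.` becomes
#' `"both"`. The `ID` attribute provides `feature_id` and the `family_id`
#' attribute, when present, the family.
#'
#' @param path Path to a GFF3 file.
#' @param strain_id Strain identifier; defaults to the first seqid.
#' @param type_map Named vector mapping GFF3 types to kinds; see
#'   [default_type_map()]. A type ending in `RNA` that is absent from the
#'   map is still treated as `"rna"`.
#' @return An `AnnotationSet`.
#' @export
read_annotation <- function(path, strain_id = NULL, type_map = default_type_map()) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L))
    stop("malformed GFF3 line ", body[which(nfield != 9L)[1L]],
         " in ", path, ": expected 9 tab-separated fields")
  region <- grep("^##sequence-region", lines, value = TRUE)
  genome_length <- NA_integer_
  if (length(region)) {
    tok <- strsplit(trimws(region[1L]), "\\s+")[[1L]]
    genome_length <- as.integer(tok[4L])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(strain_id)) {
    strain_id <- if (length(gr)) as.character(GenomicRanges::seqnames(gr)[1L])
                 else sub(" .*", "", sub("^##sequence-region\\s+", "", region[1L]))
  }
  if (length(gr) == 0L) {
    if (is.na(genome_length))
      stop("empty GFF3 without a ##sequence-region pragma: genome length unknown")
    return(annotation_set(strain_id, genome_length))
  }
  type <- as.character(gr$type)
  kind <- unname(type_map[type])
  kind[is.na(kind) & grepl("RNA$", type)] <- "rna"
  keep <- !is.na(kind)
  if (any(!keep))
    warning("skipping ", sum(!keep), " feature(s) with unmapped GFF3 type(s): ",
            paste(unique(type[!keep]), collapse = ", "))
  gr <- gr[keep]; kind <- kind[keep]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  ids[is.na(ids)] <- sprintf("feature_%04d", which(is.na(ids)))
  fam <- if (!is.null(gr$family_id)) as.character(gr$family_id)
         else rep(NA_character_, length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "both"
  features <- data.frame(
    feature_id = ids, family_id = fam, kind = kind,
    start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr),
    strand = strand, stringsAsFactors = FALSE)
  if (is.na(genome_length)) genome_length <- max(features$end)
  annotation_set(strain_id, genome_length, features)
}

#' Write an annotation set to GFF3
#'
#' Inverse of [read_annotation()]: internal 0-based half-open intervals
#' are written as 1-based closed GFF3 coordinates, with a
#' `##sequence-region` pragma carrying the genome length. Kinds map to
#' types `CDS`, `ncRNA` and `ncRNA_candidate`, which the default reader
#' maps back, so read-write round trips preserve all features.
#'
#' @param ann An `AnnotationSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "AnnotationSet"))
  type_of <- c(protein = "CDS", rna = "ncRNA", ruf = "ncRNA_candidate")
  f <- ann$features
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d", ann$strain_id, ann$genome_length))
  if (nrow(f)) {
    attrs <- ifelse(is.na(f$family_id),
                    sprintf("ID=%s", f$feature_id),
                    sprintf("ID=%s;family_id=%s", f$feature_id, f$family_id))
    strand <- ifelse(f$strand == "both", ".", f$strand)
    body <- sprintf("%s\trufscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
                    ann$strain_id, type_of[f$kind], f$start + 1L, f$end,
                    strand, attrs)
  } else body <- character()
  writeLines(c(header, body), path)
  invisible(path)
}
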