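#' Annotation set for one organism
#'
#' Holds the multiset of (protein, GO term, aspect) records for a genome.
#' Duplicate (protein, term) pairs are legitimate and contribute to
#' abundance in the census.  `proteome_size` is the number of proteins in
#' the proteome, used as the coverage denominator; it may exceed the number
#' of annotated proteins.
#'
#' @param organism_id Organism identifier.
#' @param records data.frame with columns `protein_id`, `go_id`, `aspect`.
#' @param proteome_size Count of proteins in the proteome (NA if unknown).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(organism_id, records, proteome_size = NA_integer_) {
  stopifnot(is.character(organism_id), length(organism_id) == 1L)
  if (!all(c("protein_id", "go_id", "aspect") %in% names(records))) {
    stop_("records need columns protein_id, go_id, aspect")
  }
  n_annot <- length(unique(records$protein_id))
  if (!is.na(proteome_size) && proteome_size < n_annot) {
    stop_("proteome_size (%d) smaller than the number of annotated proteins (%d)",
          proteome_size, n_annot)
  }
  structure(list(organism_id = organism_id,
                 records = records[, c("protein_id", "go_id", "aspect")],
                 proteome_size = as.integer(proteome_size)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", x$organism_id, "-", nrow(x$records), "records,",
      length(unique(x$records$protein_id)), "proteins, proteome size",
      x$proteome_size, "\n")
  invisible(x)
}

gaf_columns <- c("db", "db_object_id", "db_object_symbol", "qualifier",
                 "go_id", "db_reference", "evidence_code", "with_from",
                 "aspect", "db_object_name", "db_object_synonym",
                 "db_object_type", "taxon", "date", "assigned_by",
                 "annotation_extension", "gene_product_form_id")

#' Parse a GAF 2.x annotation file
#'
#' Loads the 17-column tab-separated Gene Ontology Annotation File format.
#' By default only molecular-function records (aspect "F") are kept and
#' records carrying a NOT qualifier are dropped.  Duplicate (protein, term)
#' pairs are retained as distinct records: they encode paralogous copies and
#' feed the abundance census.
#'
#' @param path GAF file path, or a character vector of lines.
#' @param organism_id Organism identifier; defaults to the file base name.
#' @param proteome_size Optional proteome size for the coverage denominator.
#' @param aspects Aspects to keep ("F", "P", "C").
#' @return An [annotation_set()].
#' @export
parse_gaf <- function(path, organism_id = NULL, proteome_size = NA_integer_,
                      aspects = "F") {
  from_file <- length(path) == 1L && file.exists(path)
  lines <- if (from_file) readLines(path) else path
  if (is.null(organism_id)) {
    organism_id <- if (from_file) sub("\\.gaf$", "", basename(path)) else "unknown"
  }
  data_idx <- which(!startsWith(lines, "!") & nzchar(lines))
  body <- lines[data_idx]
  # column count by separator count: trailing GAF columns are often empty
  ntab <- nchar(body) - nchar(gsub("\t", "", body, fixed = TRUE))
  if (any(ntab != 16L)) {
    first <- which(ntab != 16L)[1L]
    stop_("GAF line %d has %d columns, expected 17",
          data_idx[first], ntab[first] + 1L)
  }
  fields <- lapply(strsplit(body, "\t", fixed = TRUE), function(f) {
    c(f, rep("", 17L - length(f)))
  })
  if (length(fields)) {
    rec <- as.data.frame(do.call(rbind, fields))
    names(rec) <- gaf_columns
  } else {
    rec <- as.data.frame(matrix(character(0), 0, 17,
                                dimnames = list(NULL, gaf_columns)))
  }
  keep <- rec$aspect %in% aspects & !grepl("\\bNOT\\b", rec$qualifier)
  rec <- rec[keep, , drop = FALSE]
  annotation_set(organism_id,
                 data.frame(protein_id = rec$db_object_id,
                            go_id = rec$go_id,
                            aspect = rec$aspect),
                 proteome_size)
}

#' Write annotation sets as GAF 2.1 files
#'
#' One file per genome, named `<organism_id>.gaf`, each line carrying the 17
#' tab-separated GAF columns with aspect "F" for molecular-function records.
#' Round-trips losslessly through [parse_gaf()].
#'
#' @param annotations Named list of [annotation_set()] objects (or a
#'   `go_census_sim` from [simulate_genomes()]).
#' @param directory Output directory (created if missing).
#' @param force Overwrite existing files?
#' @return Named character vector of file paths, invisibly.
#' @export
write_gaf <- function(annotations, directory, force = FALSE) {
  if (inherits(annotations, "go_census_sim")) annotations <- annotations$annotations
  if (!length(annotations)) stop_("no annotation sets to write")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (org in names(annotations)) {
    a <- annotations[[org]]
    path <- file.path(directory, paste0(org, ".gaf"))
    if (file.exists(path) && !force) stop_("refusing to overwrite %s", path)
    rec <- a$records
    n <- nrow(rec)
    body <- if (n) {
      cols <- list(db = rep("SYNTH", n), db_object_id = rec$protein_id,
                   db_object_symbol = rec$protein_id,
                   qualifier = rep("", n), go_id = rec$go_id,
                   db_reference = rep("SYNTH_REF:0000001", n),
                   evidence_code = rep("IEA", n), with_from = rep("", n),
                   aspect = rec$aspect, db_object_name = rep("", n),
                   db_object_synonym = rep("", n),
                   db_object_type = rep("protein", n),
                   taxon = rep("taxon:0", n), date = rep("20091101", n),
                   assigned_by = rep("SYNTH", n),
                   annotation_extension = rep("", n),
                   gene_product_form_id = rep("", n))
      do.call(paste, c(cols, sep = "\t"))
    } else character(0)
    writeLines(c("!gaf-version: 2.1",
                 paste0("!generated-by: gocensus synthetic corpus (",
                        org, ")"),
                 body), path)
    paths[org] <- path
  }
  invisible(paths)
}

#' Read and write the organism metadata table
#'
#' TSV with columns organism_id, superkingdom (A/B/E), lifestyle
#' (free_living / parasite / facultative_parasite), proteome_size,
#' is_type_strain.
#'
#' @param path File path.
#' @return `read_metadata`: the metadata data.frame.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("organism_id", "superkingdom", "lifestyle", "proteome_size",
            "is_type_strain")
  if (!all(need %in% names(md))) {
    stop_("metadata needs columns: %s", paste(need, collapse = ", "))
  }
  if (!all(md$superkingdom %in% c("A", "B", "E"))) {
    stop_("superkingdom must be one of A, B, E")
  }
  md$is_type_strain <- as.logical(md$is_type_strain)
  md
}

#' @rdname read_metadata
#' @param metadata Metadata data.frame.
#' @param force Overwrite an existing file?
#' @export
write_metadata <- function(metadata, path, force = FALSE) {
  if (file.exists(path) && !force) stop_("refusing to overwrite %s", path)
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-genome horizontally-transferred-protein lists
#'
#' One plain-text file per genome (named `<organism_id>.htp`), one protein
#' identifier per line, emulating HGT-DB exports.
#'
#' @param directory Directory holding `.htp` files / to write into.
#' @return `read_hgt_lists`: named list of protein-id character vectors.
#' @export
read_hgt_lists <- function(directory) {
  files <- list.files(directory, pattern = "\\.htp$", full.names = TRUE)
  out <- lapply(files, function(f) {
    x <- readLines(f)
    x[nzchar(x)]
  })
  names(out) <- sub("\\.htp$", "", basename(files))
  out
}

#' @rdname read_hgt_lists
#' @param hgt_lists Named list of protein-id vectors.
#' @param force Overwrite existing files?
#' @export
write_hgt_lists <- function(hgt_lists, directory, force = FALSE) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (org in names(hgt_lists)) {
    path <- file.path(directory, paste0(org, ".htp"))
    if (file.exists(path) && !force) stop_("refusing to overwrite %s", path)
    writeLines(hgt_lists[[org]], path)
  }
  invisible(directory)
}
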