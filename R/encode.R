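state_alphabet <- c(as.character(0:9), LETTERS[1:22])

#' Alphanumeric symbol of an encoded character state
#'
#' States 0-9 map to the digits '0'-'9' and states 10-31 to the letters
#' 'A'-'V', giving the 32-symbol alphabet of the phylogenetic matrices.
#'
#' @param state Integer state(s) in [0, 31].
#' @return Character vector of single symbols.
#' @export
state_symbol <- function(state) {
  if (any(is.na(state)) || any(state != floor(state)) ||
      any(state < 0) || any(state > 31)) {
    stop_("state must be an integer in [0, 31]")
  }
  state_alphabet[state + 1L]
}

#' Encode raw abundances into 32 ordered character states
#'
#' Applies the log-normalisation that turns the raw census into
#' phylogenetic characters: each abundance is transformed as
#' `round(ln(g + 1) / ln(g_max + 1) * 31)` with `g_max` the single
#' matrix-wide maximum abundance, so absence maps to state 0 and the
#' heaviest cell to state 31.  The log damps unequal genome sizes and
#' heterogeneous variances; the matrix-wide `g_max` keeps states comparable
#' across genomes.  Rounding is half-up (0.5 rounds to the next state),
#' fixed so the state boundaries are reproducible.
#'
#' @param census A `go_census` (normally after HGT-term exclusion, so
#'   `g_max` is taken over the final dataset).
#' @return A `go_encoded`: list with `states` (integer matrix in [0, 31]),
#'   `symbols` (character matrix), `g_max` and `superkingdom`.
#' @export
encode_census <- function(census) {
  stopifnot(inherits(census, "go_census"))
  ab <- census$abundance
  if (!length(ab)) stop_("cannot encode an empty census")
  if (any(ab < 0)) stop_("negative abundance")
  g_max <- max(ab)
  if (g_max < 1) stop_("all abundances are zero (g_max < 1)")
  states <- round_half_up(log(ab + 1) / log(g_max + 1) * 31)
  storage.mode(states) <- "integer"
  symbols <- matrix(state_symbol(states), nrow(states),
                    dimnames = dimnames(states))
  structure(list(states = states, symbols = symbols, g_max = g_max,
                 superkingdom = census$superkingdom),
            class = "go_encoded")
}

#' @export
print.go_encoded <- function(x, ...) {
  cat("go_encoded:", nrow(x$states), "genomes x", ncol(x$states),
      "terms; g_max =", x$g_max, "\n")
  cat("  states used:", length(unique(as.vector(x$states))), "of 32\n")
  invisible(x)
}

#' Orient the encoded matrix as a character-matrix view
#'
#' The same encoded matrix feeds two reconstructions: the tree of life
#' (ToL; taxa are genomes, characters are GO-TMF terms) and the tree of
#' functions (ToF; taxa are terms, characters are genomes).  The ToF view
#' is the transpose of the ToL view; no re-encoding happens.
#'
#' @param encoded A `go_encoded` from [encode_census()].
#' @param orientation "ToL" or "ToF".
#' @return A `go_charview`: list with `states` (taxa x characters), `taxa`,
#'   `characters`, `orientation`.
#' @export
character_view <- function(encoded, orientation = c("ToL", "ToF")) {
  stopifnot(inherits(encoded, "go_encoded"))
  orientation <- match.arg(orientation)
  states <- if (orientation == "ToL") encoded$states else t(encoded$states)
  if (!length(states)) stop_("empty encoded matrix")
  structure(list(states = states,
                 taxa = rownames(states),
                 characters = colnames(states),
                 orientation = orientation),
            class = "go_charview")
}

#' @export
print.go_charview <- function(x, ...) {
  cat("go_charview (", x$orientation, "): ", length(x$taxa), " taxa x ",
      length(x$characters), " characters\n", sep = "")
  invisible(x)
}

nexus_safe <- function(labels) {
  needs <- grepl("[^A-Za-z0-9_.]", labels)
  labels[needs] <- paste0("'", gsub("'", "''", labels[needs]), "'")
  labels
}

#' Write a character-matrix view as NEXUS
#'
#' Emits a DATA block using the 32-symbol alphabet (symbols "0~9A~V"), an
#' ASSUMPTIONS block declaring the characters ordered with the ancestral
#' state fixed at V (polarity "max", the ToF convention: the most abundant
#' function is oldest) or 0 (polarity "min", the ToL convention: the
#' ancestral genome is minimal), and a comment carrying the Lundberg
#' rooting directive for PAUP*.
#'
#' @param view A `go_charview`.
#' @param polarity "max" (ancestral state V) or "min" (ancestral state 0).
#' @param path Output file, or NULL to return the text.
#' @param force Overwrite an existing file?
#' @return The NEXUS text, invisibly when written to a file.
#' @export
write_nexus <- function(view, polarity = c("max", "min"), path = NULL,
                        force = FALSE) {
  stopifnot(inherits(view, "go_charview"))
  polarity <- match.arg(polarity)
  if (anyDuplicated(view$taxa)) stop_("duplicate taxon labels")
  anc <- if (polarity == "max") "V" else "0"
  labs <- nexus_safe(view$taxa)
  pad <- formatC(labs, width = max(nchar(labs)), flag = "-")
  rows <- paste0("    ", pad, "  ",
                 apply(view$states, 1L, function(s)
                   paste(state_alphabet[s + 1L], collapse = "")))
  txt <- c("#NEXUS",
           "[ genomic census of terminal molecular-function GO terms ]",
           "BEGIN DATA;",
           sprintf("    DIMENSIONS NTAX=%d NCHAR=%d;",
                   length(view$taxa), length(view$characters)),
           "    FORMAT SYMBOLS=\"0~9A~V\" MISSING=? GAP=-;",
           "    MATRIX",
           rows,
           "    ;",
           "END;",
           "BEGIN ASSUMPTIONS;",
           "    OPTIONS DEFTYPE=ORD;",
           sprintf("    ANCSTATES lundberg_anc = %s: 1-%d;", anc,
                   length(view$characters)),
           "END;",
           "BEGIN PAUP;",
           sprintf(paste0("    [ Lundberg rooting: ROOTTREES ",
                          "ROOTMETHOD=LUNDBERG ANCSTATES=lundberg_anc; ",
                          "ancestral state %s on all characters ]"), anc),
           "END;")
  if (is.null(path)) return(txt)
  if (file.exists(path) && !force) stop_("refusing to overwrite %s", path)
  writeLines(txt, path)
  invisible(txt)
}
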