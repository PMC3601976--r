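# Sequence records and FASTA input/output.
#
# A sequence collection is an ordinary data.frame with one row per
# sequence and columns id, residues, alphabet ("nt" or "aa"), species and
# group.  The group is one of the taxon roles used by the screening
# cascade: "self" (the parasite under study), "close_relative",
# "donor_candidate", "other" or "unknown".

TAXON_GROUPS <- c("self", "close_relative", "donor_candidate", "other", "unknown")

#' Build a sequence-record data.frame
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of sequences (uppercased on entry).
#' @param alphabet "nt" or "aa"; guessed from the residues when `NULL`.
#' @param species,group per-record annotation (recycled).
#' @return data.frame with columns id, residues, alphabet, species, group.
#' @export
sequence_records <- function(id, residues, alphabet = NULL,
                             species = NA_character_, group = "unknown") {
  if (length(id) != length(residues)) stop2("id and residues differ in length")
  if (anyDuplicated(id)) {
    stop2("duplicate sequence id(s): ",
          paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  residues <- toupper(residues)
  if (any(!nzchar(residues))) stop2("empty residues are not allowed")
  if (is.null(alphabet)) {
    alphabet <- ifelse(grepl("^[ACGTN]+$", residues), "nt", "aa")
  }
  bad <- alphabet == "nt" & !grepl("^[ACGTN]+$", residues)
  if (any(bad)) stop2("non-nucleotide characters in nt record(s): ",
                      paste(id[bad], collapse = ", "))
  if (!all(group %in% TAXON_GROUPS)) stop2("unknown taxon group")
  data.frame(id = as.character(id), residues = residues,
             alphabet = alphabet,
             species = as.character(species),
             group = as.character(group),
             stringsAsFactors = FALSE)
}

#' Read a FASTA file into sequence records
#'
#' Residues are uppercased; the taxon group is "unknown" until annotated
#' with [annotate_groups()].  Duplicate ids and empty files are errors.
#'
#' @param path FASTA file.
#' @param species optional species label applied to every record.
#' @return a sequence-record data.frame (see [sequence_records()]).
#' @export
read_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop2("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop2("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(set))
  sequence_records(ids, as.character(set), species = species)
}

#' Write sequence records to FASTA
#'
#' @param records sequence-record data.frame.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build a species-to-taxon-group map
#'
#' The cascade needs at least one close relative (to veto vertically
#' inherited genes) and one donor-candidate species (the putative host
#' lineage, e.g. the rosid families that host most broomrapes).
#'
#' @param species character vector.
#' @param group matching vector of taxon groups.
#' @return data.frame with columns species, group.
#' @export
taxon_group_map <- function(species, group) {
  if (length(species) != length(group)) stop2("species/group length mismatch")
  if (anyDuplicated(species)) stop2("species mapped more than once: ",
                                    paste(species[duplicated(species)], collapse = ", "))
  if (!all(group %in% TAXON_GROUPS)) stop2("unknown taxon group in map")
  if (!any(group == "close_relative") || !any(group == "donor_candidate")) {
    stop2("map needs at least one close_relative and one donor_candidate species")
  }
  data.frame(species = as.character(species), group = as.character(group),
             stringsAsFactors = FALSE)
}

group_of_species <- function(species, taxon_map) {
  idx <- match(species, taxon_map$species)
  if (anyNA(idx)) stop2("species not in taxon map: ",
                        paste(unique(species[is.na(idx)]), collapse = ", "))
  taxon_map$group[idx]
}

#' Annotate sequence records with taxon groups from a map
#'
#' @param records sequence-record data.frame with a species column.
#' @param taxon_map output of [taxon_group_map()].
#' @return the records with the group column filled in.
#' @export
annotate_groups <- function(records, taxon_map) {
  records$group <- group_of_species(records$species, taxon_map)
  records
}
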