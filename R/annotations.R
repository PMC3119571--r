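# Static knowledge base: subdomain spans, hydrophobic region residue lists,
# numbering offsets, the clinical mutation catalog and the persistent
# hydrophilic interaction tables for the ErbB kinase family. All data ship
# as versioned CSV files under inst/extdata; a YAML override file can extend
# regions and offsets.

ERBB_KINASES <- c("EGFR", "ErbB2", "ErbB3", "ErbB4")

# Accept both the Greek-letter and the ASCII spellings of region labels.
normalize_label <- function(x) {
  x <- gsub("αC", "aC", x)
  x <- gsub("β4", "b4", x)
  x
}

annot_env <- new.env(parent = emptyenv())

annot_table <- function(name) {
  if (is.null(annot_env[[name]])) {
    annot_env[[name]] <- utils::read.csv(extdata_path(paste0(name, ".csv")),
                                         stringsAsFactors = FALSE)
  }
  annot_env[[name]]
}

split_residues <- function(x) as.integer(strsplit(x, ";", fixed = TRUE)[[1]])

#' Load user overrides for regions and numbering offsets
#'
#' The YAML file may contain `regions:` (kinase -> region -> residue list)
#' and `offsets:` (kinase -> integer) entries that extend or replace the
#' packaged data for the current session.
#'
#' @param path YAML file.
#' @return invisibly, the parsed override list.
#' @export
load_annotation_overrides <- function(path) {
  ov <- yaml::read_yaml(path)
  annot_env$overrides <- ov
  invisible(ov)
}

#' Clear annotation overrides
#' @export
clear_annotation_overrides <- function() {
  annot_env$overrides <- NULL
  invisible(NULL)
}

#' Residues of a named hydrophobic region
#'
#' Packaged regions: `C-spine`, `R-spine`, `hydrophobic-core`,
#' `dimer-interface-N`, `dimer-interface-C` and the `aC-b4` patch. Lists
#' for kinases other than EGFR were placed by family-alignment offsets and
#' are flagged provisional in the data file; pairs that the knowledge base
#' does not define raise a lookup error.
#'
#' @param kinase one of EGFR, ErbB2, ErbB3, ErbB4.
#' @param region region label (Greek or ASCII spelling).
#' @return ascending integer residue ids.
#' @export
get_region <- function(kinase, region) {
  region <- normalize_label(region)
  ov <- annot_env$overrides
  if (!is.null(ov$regions[[kinase]][[region]]))
    return(sort(as.integer(ov$regions[[kinase]][[region]])))
  tb <- annot_table("regions")
  hit <- tb[tb$kinase == kinase & tb$region == region, ]
  if (!nrow(hit)) {
    avail <- paste(tb$kinase, tb$region, sep = "/", collapse = ", ")
    abort_lookup("region (%s, %s) is not packaged; available: %s", kinase, region, avail)
  }
  sort(split_residues(hit$residues[1]))
}

#' Convert between mature-protein and alternate residue numbering
#'
#' The ErbB literature uses two numbering schemes that differ by whether the
#' signal segment is counted; for EGFR the offset is +24 (Y845 in mature
#' numbering is Y869 in the alternate scheme). Offsets for the other family
#' members are not packaged and raise a lookup error unless user-configured.
#'
#' @param kinase kinase name.
#' @param position residue number.
#' @param direction `"mature_to_alternate"` or `"alternate_to_mature"`.
#' @return converted residue number.
#' @export
map_numbering <- function(kinase, position,
                          direction = c("mature_to_alternate", "alternate_to_mature")) {
  direction <- match.arg(direction)
  ov <- annot_env$overrides
  off <- NULL
  if (!is.null(ov$offsets[[kinase]])) off <- as.integer(ov$offsets[[kinase]])
  if (is.null(off)) {
    tb <- annot_table("offsets")
    hit <- tb[tb$kinase == kinase, ]
    if (!nrow(hit))
      abort_lookup("no numbering offset packaged for %s (only: %s)",
                   kinase, paste(tb$kinase, collapse = ", "))
    off <- hit$offset[1]
  }
  if (direction == "mature_to_alternate") position + off else position - off
}

kinase_span <- function(kinase) {
  tb <- annot_table("subdomains")
  sd <- tb[tb$kinase == kinase, ]
  if (!nrow(sd)) abort_lookup("no subdomain map packaged for kinase '%s'", kinase)
  c(min(sd$start), max(sd$end))
}

#' Classify a residue position into subdomains and hydrophobic regions
#'
#' Returns every packaged subdomain interval and hydrophobic region residue
#' list containing the position; memberships can overlap (e.g. a residue in
#' both the A-loop and the hydrophobic core). Inside the kinase domain the
#' result always contains a lobe label.
#'
#' @param kinase one of EGFR, ErbB2, ErbB3, ErbB4.
#' @param position residue number (author/mature numbering).
#' @return character vector of labels.
#' @export
classify_position <- function(kinase, position) {
  span <- kinase_span(kinase)
  if (position < span[1] || position > span[2])
    abort_range("position %d outside the packaged %s span %d-%d",
                position, kinase, span[1], span[2])
  tb <- annot_table("subdomains")
  sd <- tb[tb$kinase == kinase & tb$start <= position & tb$end >= position, ]
  labels <- sd$subdomain
  rg <- annot_table("regions")
  rg <- rg[rg$kinase == kinase, ]
  for (i in seq_len(nrow(rg))) {
    if (position %in% split_residues(rg$residues[i])) labels <- c(labels, rg$region[i])
  }
  unique(labels)
}

#' Load the packaged clinical mutation catalog
#'
#' Transcribed per-tumor subdomain records for RTK kinase-domain mutations,
#' plus named records for the mutations discussed individually (L834R, the
#' exon-19-type deletion with its three printed alias spellings, T766M,
#' G776^YVMA^ and others). The `effect` column distinguishes activating,
#' loss-of-function and resistance records.
#'
#' @return data.frame with columns gene, subdomain, tumor, effect,
#'   description, aliases, citations, source.
#' @export
load_mutation_catalog <- function() {
  annot_table("mutations")
}

#' Load the persistent hydrophilic interaction table
#'
#' The curated per-kinase, per-state residue-pair interaction network for
#' the ErbB monomers, with salt bridges and hydrogen bonds distinguished
#' and homologous interactions aligned on a shared `homology_row` index.
#'
#' @return data.frame with columns homology_row, section, kinase, state,
#'   res_i, res_j, name_i, name_j, bond_type.
#' @export
load_interaction_table <- function() {
  tb <- annot_table("table4")
  parse_res <- function(x) list(name = substr(x, 1, 1),
                                id = as.integer(substr(x, 2, nchar(x))))
  p1 <- lapply(tb$partner1, parse_res)
  p2 <- lapply(tb$partner2, parse_res)
  data.frame(
    homology_row = tb$homology_row,
    section = tb$section,
    kinase = tb$kinase,
    state = tb$state,
    res_i = vapply(p1, `[[`, integer(1), "id"),
    res_j = vapply(p2, `[[`, integer(1), "id"),
    name_i = vapply(p1, `[[`, character(1), "name"),
    name_j = vapply(p2, `[[`, character(1), "name"),
    bond_type = ifelse(tb$salt_bridge, "salt-bridge", "h-bond"),
    stringsAsFactors = FALSE
  )
}

#' Interactions conserved across kinases in a conformational state
#'
#' A homology row is conserved for a state when an entry exists for every
#' requested kinase at that row and state. By default conservation is
#' state-characteristic: rows that also appear in the opposite state for
#' any requested kinase are excluded, which reproduces the six interactions
#' that define the active-state network across EGFR/ErbB2/ErbB4 (a plain
#' intersection additionally picks up the state-independent A815-N818 bond).
#'
#' @param entries data.frame from [load_interaction_table()].
#' @param state `"active"` or `"inactive"`.
#' @param kinases character vector of kinases that must all carry the row.
#' @param state_specific exclude rows present in the opposite state for any
#'   requested kinase (default `TRUE`).
#' @return integer vector of conserved homology rows (sorted).
#' @export
conserved_interactions <- function(entries, state, kinases, state_specific = TRUE) {
  if (!length(kinases)) abort_usage("at least one kinase must be requested")
  sub <- entries[entries$state == state & entries$kinase %in% kinases, ]
  tab <- table(unique(sub[, c("homology_row", "kinase")])$homology_row)
  rows <- as.integer(names(tab)[tab == length(unique(kinases))])
  if (state_specific) {
    other <- setdiff(c("active", "inactive"), state)
    opp <- entries[entries$state == other & entries$kinase %in% kinases, ]
    rows <- setdiff(rows, unique(opp$homology_row))
  }
  sort(rows)
}
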