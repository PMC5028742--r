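# io_model: domain types, readers/writers, design validation, taxonomic collapse
#
# Conventions used throughout the package:
#  * count matrices are OTU x replicate (rows = OTUs, columns = PCR replicates),
#    matching the orientation of a raw OTU table on disk;
#  * incidence matrices are unit x feature (rows = bottles/transects/sites,
#    columns = OTUs/families/niches), matching the vegan convention.

#' Validate an OTU-by-replicate count matrix
#'
#' Checks the invariants of the pipeline's raw input: unique identifiers on
#' both axes and non-negative integral counts. Replicate columns with no
#' reads at all are dropped with a warning (a replicate that produced no
#' sequence cannot be retained).
#'
#' @param m numeric matrix with OTU ids as rownames and replicate ids as
#'   colnames.
#' @return the validated matrix, with integer storage mode.
#' @export
as_count_matrix <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix needs OTU rownames and replicate colnames")
  dup <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup))
    stop(sprintf("duplicate OTU id(s): %s", paste(dup, collapse = ", ")))
  dup <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup))
    stop(sprintf("duplicate replicate id(s): %s", paste(dup, collapse = ", ")))
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("invalid count at OTU '%s', replicate '%s': %s",
                 rownames(m)[i], colnames(m)[j], format(m[i, j])))
  }
  empty <- colSums(m) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d replicate(s) with zero total reads: %s",
                    sum(empty), paste(colnames(m)[empty], collapse = ", ")))
    m <- m[, !empty, drop = FALSE]
  }
  storage.mode(m) <- "integer"
  m
}

#' Read an OTU-by-replicate count table
#'
#' The table is tab-separated with a mandatory header row of replicate ids;
#' the first column holds OTU ids. All remaining cells must be non-negative
#' integers. Malformed cells are reported with their OTU and replicate ids.
#'
#' @param path path to a UTF-8 TSV file.
#' @return integer matrix (OTU x replicate).
#' @export
load_count_table <- function(path) {
  raw <- read_tsv(path, colClasses = "character")
  if (ncol(raw) < 2)
    stop("count table needs an OTU id column plus at least one replicate column")
  otu_ids <- as.character(raw[[1]])
  m <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
              dimnames = list(otu_ids, colnames(raw)[-1]))
  for (j in seq_len(ncol(raw) - 1L)) {
    v <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric count at OTU '%s', replicate '%s': '%s'",
                   otu_ids[bad[1]], colnames(raw)[j + 1L],
                   ifelse(is.na(v[bad[1]]), "NA", v[bad[1]])))
    m[, j] <- num
  }
  as_count_matrix(m)
}

#' Write an OTU-by-replicate count table
#'
#' @param counts count matrix as returned by [load_count_table()].
#' @param path output path; the writer is bit-stable for identical inputs.
#' @export
write_count_table <- function(counts, path) {
  write_tsv(matrix_to_df(counts, "otu_id"), path)
}

design_columns <- c("replicate_id", "site", "pair", "urban", "transect",
                    "bottle", "pcr_rep", "imperviousness")

#' Validate a replicated sampling design
#'
#' The design table has one row per PCR replicate and encodes the nested
#' hierarchy site pair > site > transect > bottle (water sample) > PCR
#' replicate, plus per-site watershed imperviousness (percent, a proxy for
#' urbanization). Validation checks:
#' * required columns, unique replicate ids;
#' * `urban` is `"less"` or `"more"` and constant within a site;
#' * imperviousness is in \[0, 100\] and constant within a site;
#' * every transect carries exactly one bottle;
#' * each pair holds one more-urban and one less-urban site (warning and
#'   `paired_ok = FALSE` in the summary otherwise, so pairwise analyses can
#'   be skipped);
#' * the number of PCR replicates per bottle (warning if ragged).
#'
#' Validation is idempotent and independent of row order.
#'
#' @param design data.frame with columns `replicate_id`, `site`, `pair`,
#'   `urban`, `transect`, `bottle`, `pcr_rep`, `imperviousness`.
#' @return the design with class `"edna_design"` and a `"summary"`
#'   attribute (see [design_summary()]).
#' @export
validate_design <- function(design) {
  miss <- setdiff(design_columns, names(design))
  if (length(miss))
    stop(sprintf("design is missing column(s): %s", paste(miss, collapse = ", ")))
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  dup <- unique(design$replicate_id[duplicated(design$replicate_id)])
  if (length(dup))
    stop(sprintf("duplicate replicate id(s): %s", paste(dup, collapse = ", ")))
  if (!all(design$urban %in% c("less", "more")))
    stop("urban must be 'less' or 'more'")
  imp <- design$imperviousness
  if (!is.numeric(imp) || any(is.na(imp)) || any(imp < 0 | imp > 100))
    stop("imperviousness must be numeric in [0, 100]")

  per_site <- function(col) tapply(design[[col]], design$site,
                                   function(v) length(unique(v)))
  if (any(per_site("imperviousness") > 1))
    stop(sprintf("inconsistent imperviousness within site(s): %s",
                 paste(names(which(per_site("imperviousness") > 1)), collapse = ", ")))
  if (any(per_site("urban") > 1) || any(per_site("pair") > 1))
    stop("urban class and pair must be constant within a site")

  # bottles nested 1:1 in transects (a transect is sampled by one bottle)
  tb <- unique(design[, c("site", "transect", "bottle")])
  if (anyDuplicated(paste(tb$site, tb$transect)) ||
      anyDuplicated(paste(tb$site, tb$bottle)))
    stop("every transect must carry exactly one bottle (and vice versa)")

  paired_ok <- TRUE
  site_tab <- unique(design[, c("site", "pair", "urban")])
  for (p in unique(site_tab$pair)) {
    cls <- sort(site_tab$urban[site_tab$pair == p])
    if (!identical(cls, c("less", "more"))) {
      warning(sprintf("pair '%s' lacks one site of each urban class; pairwise analyses will be skipped", p))
      paired_ok <- FALSE
    }
  }

  K <- table(design$bottle)
  if (length(unique(as.integer(K))) > 1)
    warning(sprintf("unequal PCR replicate counts across bottles (%s)",
                    paste(sort(unique(as.integer(K))), collapse = "/")))
  tcount <- tapply(tb$transect, tb$site, length)
  if (length(unique(as.integer(tcount))) > 1)
    warning(sprintf("unequal transect counts across sites (%s); a water sample may have been lost",
                    paste(sort(unique(as.integer(tcount))), collapse = "/")))

  summ <- list(
    n_replicates = nrow(design),
    n_bottles = length(unique(design$bottle)),
    n_transects = nrow(tb),
    n_sites = length(unique(design$site)),
    n_pairs = length(unique(design$pair)),
    pcr_reps = sort(unique(as.integer(K))),
    paired_ok = paired_ok
  )
  attr(design, "summary") <- summ
  class(design) <- unique(c("edna_design", class(design)))
  design
}

#' Summary counts of a validated design
#'
#' @param design an `edna_design` (or raw design data.frame, validated on
#'   the fly).
#' @return list with replicate/bottle/transect/site/pair counts, the
#'   per-bottle PCR replicate count(s) and the `paired_ok` flag.
#' @export
design_summary <- function(design) {
  if (is.null(attr(design, "summary"))) design <- validate_design(design)
  attr(design, "summary")
}

#' Read and validate a sampling design table
#'
#' @param path TSV with one row per PCR replicate (see [validate_design()]).
#' @return validated `edna_design`.
#' @export
load_design <- function(path) {
  df <- read_tsv(path)
  validate_design(df)
}

#' @rdname load_design
#' @param design validated design.
#' @export
write_design <- function(design, path) {
  write_tsv(as.data.frame(design)[, design_columns], path)
}

#' Write a JSON summary of a validated design
#'
#' @inheritParams write_design
#' @export
write_design_summary <- function(design, path) {
  jsonlite::write_json(design_summary(design), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read an OTU taxonomy table
#'
#' Columns: `otu_id`, `phylum`, `class`, `order`, `family`; any rank may be
#' missing (`NA` or empty). Used to collapse OTU-level incidence to family
#' level.
#'
#' @param path TSV path.
#' @return data.frame, one row per OTU.
#' @export
load_taxonomy <- function(path) {
  tax <- read_tsv(path)
  need <- c("otu_id", "phylum", "class", "order", "family")
  miss <- setdiff(need, names(tax))
  if (length(miss))
    stop(sprintf("taxonomy is missing column(s): %s", paste(miss, collapse = ", ")))
  dup <- unique(tax$otu_id[duplicated(tax$otu_id)])
  if (length(dup))
    stop(sprintf("duplicate otu_id in taxonomy: %s", paste(dup, collapse = ", ")))
  tax
}

#' @rdname load_taxonomy
#' @param tax taxonomy data.frame.
#' @export
write_taxonomy <- function(tax, path) write_tsv(tax, path)

# controlled vocabularies for the life-history attributes
trait_alphabets <- list(
  category = c("epifauna", "infauna", "demersal", "pelagic", "terrestrial"),
  habitat  = c("terrestrial", "freshwater", "intertidal", "subtidal"),
  mobility = c("motile", "sessile")
)

#' Read a family life-history trait table
#'
#' Columns `family`, `category`, `habitat`, `mobility`; multi-valued
#' attributes are ";"-separated (a family spanning several attributes is
#' listed with all of them). Tokens are checked against the controlled
#' vocabularies (Category: epifauna/infauna/demersal/pelagic/terrestrial;
#' Habitat: terrestrial/freshwater/intertidal/subtidal; Mobility:
#' motile/sessile) and each attribute set must be non-empty.
#'
#' @param path TSV path.
#' @return data.frame, one row per family.
#' @export
load_traits <- function(path) {
  tr <- read_tsv(path)
  validate_traits(tr)
}

#' @rdname load_traits
#' @param traits trait data.frame.
#' @export
write_traits <- function(traits, path) write_tsv(traits, path)

#' @rdname load_traits
#' @export
validate_traits <- function(traits) {
  need <- c("family", "category", "habitat", "mobility")
  miss <- setdiff(need, names(traits))
  if (length(miss))
    stop(sprintf("trait table is missing column(s): %s", paste(miss, collapse = ", ")))
  dup <- unique(traits$family[duplicated(traits$family)])
  if (length(dup))
    stop(sprintf("duplicate family in trait table: %s", paste(dup, collapse = ", ")))
  for (attrib in c("category", "habitat", "mobility")) {
    sets <- split_tokens(traits[[attrib]])
    if (any(lengths(sets) == 0))
      stop(sprintf("empty %s attribute set for family '%s'",
                   attrib, traits$family[which(lengths(sets) == 0)[1]]))
    unknown <- setdiff(unique(unlist(sets)), trait_alphabets[[attrib]])
    if (length(unknown))
      stop(sprintf("unknown %s token(s): %s", attrib,
                   paste(unknown, collapse = ", ")))
  }
  traits
}

#' Presence/absence from counts
#'
#' @param x numeric matrix or data.frame.
#' @return integer 0/1 matrix of the same shape.
#' @export
as_incidence <- function(x) {
  m <- as.matrix(x)
  out <- (m > 0) * 1L
  dimnames(out) <- dimnames(m)
  out
}

# union of rows within groups: unit x feature incidence -> group x feature
aggregate_incidence <- function(inc, groups) {
  groups <- as.character(groups)
  g <- rowsum(as_incidence(inc), groups, reorder = FALSE)
  as_incidence(g)
}

#' Collapse OTU-level incidence to family level
#'
#' A family is present in a unit iff at least one member OTU is present.
#' OTUs lacking a family annotation (absent from the taxonomy, or with a
#' missing `family` field, e.g. resolvable only above family rank) are
#' dropped; the number dropped is recorded in the `"n_dropped"` attribute.
#'
#' @param inc unit x OTU incidence matrix.
#' @param tax taxonomy table (see [load_taxonomy()]).
#' @return unit x family incidence matrix with attribute `n_dropped`.
#' @export
collapse_to_family <- function(inc, tax) {
  inc <- as_incidence(inc)
  fam <- tax$family[match(colnames(inc), tax$otu_id)]
  keep <- !is.na(fam) & nzchar(fam)
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    warning("no OTU in the incidence matrix has a family annotation")
    out <- matrix(0L, nrow(inc), 0, dimnames = list(rownames(inc), character(0)))
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  sub <- inc[, keep, drop = FALSE]
  byfam <- rowsum(t(sub), fam[keep], reorder = TRUE)   # family x unit
  out <- as_incidence(t(byfam))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Site-level incidence from bottle/transect-level incidence
#'
#' A feature is present at a site iff present in at least one of its
#' bottles (equivalently transects, as each transect carries one bottle).
#'
#' @param inc bottle x feature incidence; rownames are bottle ids.
#' @param design validated design.
#' @return site x feature incidence.
#' @export
site_incidence <- function(inc, design) {
  design <- if (inherits(design, "edna_design")) design else validate_design(design)
  map <- unique(as.data.frame(design)[, c("bottle", "site")])
  site <- map$site[match(rownames(inc), map$bottle)]
  if (anyNA(site))
    stop(sprintf("bottle(s) not in design: %s",
                 paste(rownames(inc)[is.na(site)], collapse = ", ")))
  aggregate_incidence(inc, site)
}

# per-site covariate table (one row per site, design row order)
site_table <- function(design) {
  unique(as.data.frame(design)[, c("site", "pair", "urban", "imperviousness")])
}
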