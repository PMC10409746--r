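# Strain rosters and community designs.
#
# A roster is a data.frame with one row per strain:
#   strain_id  short letter code ("B.ca", "E.fa", ...)
#   full_name  species / strain name
#   n_16S      16S rRNA gene copies per genome (integer >= 1)
#   dtl        detection limit on the raw qPCR scale, copies per 5 ng gDNA (>= 0)
#
# A community design is a roster plus an optional dropout_of strain: the
# community contains every roster member except the dropped strain.

#' Construct and validate a strain roster
#'
#' @param strain_id character vector of unique short strain codes.
#' @param full_name character vector of species names.
#' @param n_16S integer vector, 16S rRNA gene copies per genome (>= 1).
#' @param dtl numeric vector, strain-specific qPCR detection limit in copies
#'   per 5 ng gDNA template (>= 0). Values at or above the DTL count as
#'   detected (the limit is inclusive-detectable).
#' @return a `data.frame` of class `strain_roster`.
#' @export
strain_roster <- function(strain_id, full_name = strain_id,
                          n_16S = 5L, dtl = 100) {
  n <- length(strain_id)
  n_16S <- rep_len(n_16S, n)
  dtl <- rep_len(dtl, n)
  full_name <- rep_len(full_name, n)
  if (anyDuplicated(strain_id)) {
    stopf("duplicate strain_id in roster: %s",
          paste(unique(strain_id[duplicated(strain_id)]), collapse = ", "))
  }
  if (any(n_16S < 1)) stopf("n_16S must be >= 1 for every strain")
  if (any(dtl < 0)) stopf("dtl must be >= 0 for every strain")
  out <- data.frame(strain_id = as.character(strain_id),
                    full_name = as.character(full_name),
                    n_16S = as.integer(n_16S),
                    dtl = as.numeric(dtl),
                    stringsAsFactors = FALSE)
  class(out) <- c("strain_roster", "data.frame")
  out
}

#' Default twelve-member synthetic gut community roster
#'
#' The twelve members of the Oligo-Mouse-Microbiota (OMM12) community with
#' their conventional letter codes. The per-strain 16S copy numbers and qPCR
#' detection limits are *placeholders* in a plausible range: they are
#' laboratory-specific calibration inputs that users must replace with their
#' own assay values (see `read_roster_config()`).
#'
#' @return a `strain_roster` with 12 strains.
#' @export
omm12_roster <- function() {
  strain_roster(
    strain_id = c("C.in", "B.ca", "L.re", "B.an", "M.in", "F.pl",
                  "E.cl", "A.muc", "T.mu", "B.co", "E.fa", "A.mur"),
    full_name = c("Clostridium innocuum I46",
                  "Bacteroides caecimuris I48",
                  "Limosilactobacillus reuteri I49",
                  "Bifidobacterium longum subsp. animalis YL2",
                  "Muribaculum intestinale YL27",
                  "Flavonifractor plautii YL31",
                  "Enterocloster clostridioformis YL32",
                  "Akkermansia muciniphila YL44",
                  "Turicimonas muris YL45",
                  "Blautia coccoides YL58",
                  "Enterococcus faecalis KB1",
                  "Acutalibacter muris KB18"),
    # placeholder assay calibration values -- replace with lab-specific ones
    n_16S = c(5L, 4L, 6L, 3L, 2L, 5L, 5L, 3L, 3L, 6L, 4L, 5L),
    dtl   = c(100, 50, 100, 100, 150, 100, 100, 50, 100, 100, 50, 150)
  )
}

#' Define a community as a roster minus an optional dropout strain
#'
#' @param roster a `strain_roster`.
#' @param dropout_of strain_id of the removed strain, or `NULL` for the full
#'   consortium.
#' @return list of class `community_design` with elements `roster`,
#'   `dropout_of` and `members` (expected composition).
#' @export
community_design <- function(roster, dropout_of = NULL) {
  stopifnot(inherits(roster, "strain_roster"))
  if (!is.null(dropout_of)) {
    if (length(dropout_of) != 1L || !dropout_of %in% roster$strain_id) {
      stopf("dropout_of '%s' is not a member of the roster",
            paste(dropout_of, collapse = ","))
    }
  }
  members <- setdiff(roster$strain_id, dropout_of)
  structure(list(roster = roster, dropout_of = dropout_of, members = members),
            class = "community_design")
}

#' Community label used in sample metadata
#'
#' `"full"` for the complete consortium, otherwise `"drop_<strain>"`.
#' @param design a `community_design` or a dropout strain_id (`NULL` = full).
#' @return character label.
#' @export
community_label <- function(design) {
  drop <- if (inherits(design, "community_design")) design$dropout_of else design
  if (is.null(drop) || is.na(drop) || identical(drop, "full")) "full"
  else paste0("drop_", drop)
}

#' Read a roster configuration file (JSON or YAML)
#'
#' The file must provide per-strain `strain_id`, `n_16S` and `dtl` (and may
#' provide `full_name`). This is the channel for supplying laboratory-specific
#' 16S copy numbers and detection limits.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a `strain_roster`.
#' @export
read_roster_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("reading YAML rosters requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  st <- cfg$strains %||% cfg
  strain_roster(strain_id = st$strain_id,
                full_name = st$full_name %||% st$strain_id,
                n_16S = st$n_16S, dtl = st$dtl)
}

#' @export
print.strain_roster <- function(x, ...) {
  cat(sprintf("strain roster: %d strains\n", nrow(x)))
  NextMethod()
}
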