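# Occurrence curation: deterministic, auditable cleaning and labelling
# rules applied before any rate estimation.

QUALIFIER_TOKENS <- c("cf.", "aff.", "?", "informal", "ex. gr.", "\"\"")

#' Clean a fossil occurrence table
#'
#' Applies the standard genus-level cleaning rules and logs every rejection
#' with the rule that fired:
#' \itemize{
#'   \item `ambiguous_genus`: missing or empty genus name (unambiguous
#'     genera with open species names, e.g. "sp.", are kept upstream of
#'     this table and are unaffected);
#'   \item `terrestrial`: `environment == "terrestrial"`;
#'   \item `qualifier`: open-nomenclature qualifier (`cf.`, `aff.`, `?`,
#'     `informal`, `ex. gr.`) where the primary and accepted genus names
#'     are identical; rows whose names differ record a reassignment and
#'     are retained;
#'   \item `age_span`: temporal uncertainty strictly greater than
#'     `max_span` Myr for rows not resolved to an international stage (a
#'     ~15 Myr Guadalupian row is dropped while a ~18 Myr Norian row,
#'     being a single international stage, is kept);
#'   \item `bad_age`: unparseable or inverted age interval.
#' }
#'
#' @param records occurrence data frame (see [emit_occurrence_table()] for
#'   the column dialect).
#' @param max_span maximum allowed `max_ma - min_ma` (Myr) for rows not
#'   from an international stage; the comparison is strict (`>`).
#' @return list with `kept` (cleaned records) and `log` (data frame
#'   `row`, `rule`); `nrow(kept) + nrow(log) == nrow(records)`.
#' @export
clean_occurrences <- function(records, max_span = 10) {
  n <- nrow(records)
  rule <- rep(NA_character_, n)
  max_ma <- suppressWarnings(as.numeric(records$max_ma))
  min_ma <- suppressWarnings(as.numeric(records$min_ma))
  bad_age <- is.na(max_ma) | is.na(min_ma) | max_ma <= min_ma
  rule[bad_age] <- "bad_age"

  genus <- trimws(as.character(records$genus))
  amb <- is.na(genus) | genus == ""
  rule[is.na(rule) & amb] <- "ambiguous_genus"

  terr <- !is.na(records$environment) & records$environment == "terrestrial"
  rule[is.na(rule) & terr] <- "terrestrial"

  reso <- trimws(as.character(records$primary_reso %||% rep("", n)))
  accepted <- trimws(as.character(records$accepted_genus %||% genus))
  qual <- reso %in% QUALIFIER_TOKENS & genus == accepted
  rule[is.na(rule) & qual] <- "qualifier"

  intl <- as.logical(records$is_international_stage %||% rep(TRUE, n))
  span <- (max_ma - min_ma) > max_span & !intl
  rule[is.na(rule) & !is.na(span) & span] <- "age_span"

  drop <- !is.na(rule)
  list(
    kept = records[!drop, , drop = FALSE],
    log = data.frame(row = which(drop), rule = rule[drop],
                     stringsAsFactors = FALSE)
  )
}

#' Strip or promote a bracketed subgenus name
#'
#' "Genus (Subgenus)" names are either reduced to the outer genus
#' (`delete_bracket`) or, when the subgenus is on a user-supplied
#' promotion list, upgraded so the subgenus becomes the genus (`promote`).
#'
#' @param name taxon name(s).
#' @param mode `"delete_bracket"` or `"promote"`.
#' @param promote_list character vector of subgenus names to upgrade when
#'   `mode = "promote"`; subgenera not on the list fall back to the outer
#'   genus.
#' @return cleaned name(s).
#' @export
#' @examples
#' strip_subgenus("Neomegalodon (Rossiodus)", "delete_bracket")
#' strip_subgenus("Neomegalodon (Rossiodus)", "promote", "Rossiodus")
strip_subgenus <- function(name, mode = c("delete_bracket", "promote"),
                           promote_list = character(0)) {
  mode <- match.arg(mode)
  stopifnot(all(nzchar(name)))
  n_open <- lengths(regmatches(name, gregexpr("(", name, fixed = TRUE)))
  n_close <- lengths(regmatches(name, gregexpr(")", name, fixed = TRUE)))
  if (any(n_open != n_close)) {
    stop("unbalanced brackets in: ",
         paste(name[n_open != n_close], collapse = ", "))
  }
  outer <- trimws(sub("\\s*\\(.*\\)\\s*", "", name))
  inner <- ifelse(grepl("\\(", name),
                  sub(".*\\(\\s*([^)]*?)\\s*\\).*", "\\1", name), NA_character_)
  if (mode == "delete_bracket") {
    outer
  } else {
    ifelse(!is.na(inner) & inner %in% promote_list, inner, outer)
  }
}

#' Flag occurrences outside a genus's stratigraphic density interval
#'
#' For each genus, the empirical distribution of occurrence midpoint ages
#' defines its stratigraphic range; occurrences strictly outside the
#' central `density` quantile interval are flagged as doubtful. Flagging
#' is deterministic; single-occurrence genera are never flagged.
#'
#' @param records occurrence table with `genus`, `max_ma`, `min_ma`.
#' @param density central density mass retained (default 0.90).
#' @return logical vector, `TRUE` for flagged rows.
#' @export
flag_range_outliers <- function(records, density = 0.90) {
  stopifnot_scalar_prob(density, "density")
  mid <- (records$max_ma + records$min_ma) / 2
  flag <- logical(nrow(records))
  a <- (1 - density) / 2
  for (g in unique(records$genus)) {
    rows <- which(records$genus == g)
    if (length(rows) < 2L) next
    qs <- stats::quantile(mid[rows], c(a, 1 - a), names = FALSE, type = 7)
    flag[rows] <- mid[rows] < qs[1] | mid[rows] > qs[2]
  }
  flag
}

#' Generate age-randomized replicate datasets
#'
#' Produces `n_replicates` copies of the table in which every collection
#' receives one age drawn uniformly from its stratigraphic interval and
#' all occurrences of that collection share the drawn (coeval) age, the
#' standard device for propagating stage-level age uncertainty into the
#' rate analyses.
#'
#' @param records cleaned occurrence table with `collection_no`, `max_ma`,
#'   `min_ma`.
#' @param n_replicates number of replicates (default 10).
#' @param rng_seed integer seed; fixed seed gives bit-identical output.
#' @return list of `n_replicates` data frames, each `records` plus an
#'   `age` column.
#' @export
randomize_ages <- function(records, n_replicates = 10, rng_seed = NULL) {
  colls <- unique(records$collection_no)
  ci <- match(records$collection_no, colls)
  lo <- tapply(records$min_ma, ci, max)
  hi <- tapply(records$max_ma, ci, min)
  with_seed(rng_seed, {
    lapply(seq_len(n_replicates), function(r) {
      draw <- stats::runif(length(colls), pmin(lo, hi), pmax(lo, hi))
      out <- records
      out$age <- draw[ci]
      out
    })
  })
}

#' Load the packaged ecological-lifestyle lookup table
#'
#' Maps genera (or, as a fallback, orders) to lifestyle labels: bivalves
#' to epibyssate / cemented / reclining / shallow_infaunal / deep_infaunal,
#' brachiopods to pedicle_attached / cemented / reclining / infaunal.
#'
#' @param path optional CSV override with columns `taxon`, `level`,
#'   `class`, `eco_class`.
#' @return data frame.
#' @export
load_eco_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "eco_classes.csv", package = "paleodiv")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load the packaged brachiopod order split around the end-Permian event
#'
#' Orders that went extinct in the Permian-Triassic mass extinction
#' (`PT_e`) versus those that survived it or originated afterwards
#' (`PT_s`).
#'
#' @param path optional CSV override with columns `order`, `group`.
#' @return data frame; the two groups are disjoint.
#' @export
load_pt_split <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pt_split.csv", package = "paleodiv")
  }
  ps <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(ps$order)) stop("PT split groups must be disjoint")
  ps
}

#' Assign ecological lifestyle labels
#'
#' Pure lookup: a genus-level entry wins over an order-level entry;
#' unmatched taxa get `"unknown"`. A roll-up column classifies each label
#' as epifaunal (epibyssate, cemented, reclining, pedicle_attached) or
#' infaunal (shallow/deep infaunal, infaunal).
#'
#' @param records occurrence table with `genus` (or `accepted_genus`) and
#'   `order` columns.
#' @param table lookup from [load_eco_table()].
#' @return `records` with `eco_class` and `tier` (epifaunal / infaunal /
#'   unknown) columns.
#' @export
assign_ecology <- function(records, table = load_eco_table()) {
  genus <- records$accepted_genus %||% records$genus
  g_tab <- table[table$level == "genus", ]
  o_tab <- table[table$level == "order", ]
  eco <- g_tab$eco_class[match(genus, g_tab$taxon)]
  miss <- is.na(eco)
  eco[miss] <- o_tab$eco_class[match(records$order[miss], o_tab$taxon)]
  eco[is.na(eco)] <- "unknown"
  epif <- c("epibyssate", "cemented", "reclining", "pedicle_attached")
  inf <- c("shallow_infaunal", "deep_infaunal", "infaunal")
  records$eco_class <- eco
  records$tier <- ifelse(eco %in% epif, "epifaunal",
                         ifelse(eco %in% inf, "infaunal", "unknown"))
  records
}

#' Assign brachiopod orders to the end-Permian victim/survivor split
#'
#' @param records occurrence table with an `order` column.
#' @param split lookup from [load_pt_split()].
#' @return `records` with a `pt_group` column (`PT_e`, `PT_s`, or `NA`
#'   with a warning for orders in neither set).
#' @export
assign_pt_group <- function(records, split = load_pt_split()) {
  grp <- split$group[match(records$order, split$order)]
  brach <- !is.na(records$class) & records$class == "Brachiopoda"
  if (any(brach & is.na(grp))) {
    warning("orders not in either PT group: ",
            paste(unique(records$order[brach & is.na(grp)]), collapse = ", "))
  }
  records$pt_group <- grp
  records
}
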