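# ROESY cross-peak contact tables and the radial localization score.
#
# A cross-peak between a solute proton and a surfactant proton places the
# two within roughly 5 angstroms. Classifying the surfactant protons into
# radial regions of the micelle (hydrophobic chain, terminal methyl,
# spacer, headgroup) turns a contact list into a statement about where the
# solute sits: mostly-chain contacts mean the proton is buried in the
# core, mostly-headgroup contacts mean it sits at the surface.

.SOLUTE_LABELS <- paste0("H", 1:22)
.SURFACTANT_LABELS <- paste0("H", letters[1:6])
.REGIONS <- c("chain", "terminal_methyl", "spacer", "headgroup")
.CORE_REGIONS <- c("chain", "terminal_methyl")
.SURFACE_REGIONS <- c("spacer", "headgroup")

#' Construct a validated ROESY contact table
#'
#' @param entries Data frame with columns `solute_proton` (H1-H22),
#'   `surfactant_proton` (Ha-Hf) and optionally `intensity` (>= 0,
#'   default 1).
#' @param concentration_mM,temperature_K Optional condition metadata.
#' @return An object of class `contact_table` (a data frame with metadata
#'   attributes).
#' @export
contact_table <- function(entries, concentration_mM = NA_real_,
                          temperature_K = NA_real_) {
  stopifnot(is.data.frame(entries))
  need <- c("solute_proton", "surfactant_proton")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns solute_proton and surfactant_proton",
         call. = FALSE)
  }
  if (!("intensity" %in% names(entries))) entries$intensity <- rep(1, nrow(entries))
  entries <- entries[, c("solute_proton", "surfactant_proton", "intensity")]
  if (nrow(entries) > 0L) {
    bad <- setdiff(unique(entries$solute_proton), .SOLUTE_LABELS)
    if (length(bad) > 0L) {
      stop(sprintf("unknown solute proton label(s): %s (expected H1-H22)",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    bad <- setdiff(unique(entries$surfactant_proton), .SURFACTANT_LABELS)
    if (length(bad) > 0L) {
      stop(sprintf("unknown surfactant proton label(s): %s (expected Ha-Hf)",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (any(entries$intensity < 0)) {
      stop("intensities must be non-negative", call. = FALSE)
    }
    key <- paste(entries$solute_proton, entries$surfactant_proton)
    if (anyDuplicated(key)) {
      stop(sprintf("duplicate contact pair(s): %s",
                   paste(unique(key[duplicated(key)]), collapse = ", ")),
           call. = FALSE)
    }
  }
  rownames(entries) <- NULL
  structure(entries, class = c("contact_table", "data.frame"),
            concentration_mM = concentration_mM,
            temperature_K = temperature_K)
}

#' Read / write a contact table as CSV
#'
#' CSV columns are `solute_proton,surfactant_proton,intensity` (intensity
#' optional on read, defaulting to 1).
#'
#' @param file CSV path.
#' @param concentration_mM,temperature_K Metadata attached on read.
#' @return [parse_contact_table()] returns a `contact_table`.
#' @export
parse_contact_table <- function(file, concentration_mM = NA_real_,
                                temperature_K = NA_real_) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  contact_table(df, concentration_mM = concentration_mM,
                temperature_K = temperature_K)
}

#' @rdname parse_contact_table
#' @param table A `contact_table` to write.
#' @export
write_contact_table <- function(table, file) {
  stopifnot(inherits(table, "contact_table"))
  write.csv(as.data.frame(table), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.contact_table <- function(x, ...) {
  conc <- attr(x, "concentration_mM")
  cat(sprintf("<contact_table> %d cross-peak(s)%s\n", nrow(x),
              if (!is.na(conc)) sprintf(" at %g mM surfactant", conc) else ""))
  if (nrow(x) > 0L) print.data.frame(x)
  invisible(x)
}

#' Surfactant proton -> micelle region map
#'
#' The default follows the structural assignment of the 14-6-14 gemini
#' surfactant: `Ha`, `Hb`, `Hc` lie along the hydrophobic tetradecyl
#' chains, while `Hd`, `He`, `Hf` sit at or next to the quaternary-ammonium
#' headgroups and the spacer that joins them. Note that assignments for
#' mid-chain protons such as `Hc` are genuinely ambiguous (chain vs.
#' spacer-adjacent) and should be treated as configuration, not fact;
#' supply your own map to explore the sensitivity.
#'
#' @param map Named character vector surfactant label -> region; regions
#'   must be among `chain`, `terminal_methyl`, `spacer`, `headgroup`.
#' @return A validated named character vector of class `region_map`.
#' @export
region_map <- function(map) {
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    stop("`map` must be a named vector (surfactant proton -> region)",
         call. = FALSE)
  }
  bad <- setdiff(names(map), .SURFACTANT_LABELS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown surfactant proton label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unname(map), .REGIONS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown region(s): %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(.REGIONS, collapse = ", ")), call. = FALSE)
  }
  structure(map, class = "region_map")
}

#' @rdname region_map
#' @export
default_region_map <- function() {
  region_map(c(Ha = "chain", Hb = "chain", Hc = "chain",
               Hd = "headgroup", He = "headgroup", Hf = "headgroup"))
}

#' Read a region map from JSON
#' @param file JSON file of label -> region pairs.
#' @return A `region_map`.
#' @export
read_region_map <- function(file) {
  m <- jsonlite::read_json(file, simplifyVector = TRUE)
  region_map(unlist(m))
}

#' Contacts per solute proton, aggregated by micelle region
#'
#' @param table A `contact_table`.
#' @param regions A `region_map` covering every surfactant label present.
#' @param weighted If `TRUE`, sum intensities instead of counting contacts.
#' @return Matrix (solute protons x regions) of contact counts (or
#'   intensity sums); zero-row tables give a 0 x 4 matrix.
#' @export
region_summary <- function(table, regions = default_region_map(),
                           weighted = FALSE) {
  stopifnot(inherits(table, "contact_table"))
  regions <- region_map(unclass(regions))
  uncovered <- setdiff(unique(table$surfactant_proton), names(regions))
  if (length(uncovered) > 0L) {
    stop(sprintf("surfactant proton(s) not covered by the region map: %s",
                 paste(uncovered, collapse = ", ")), call. = FALSE)
  }
  protons <- unique(table$solute_proton)
  out <- matrix(0, nrow = length(protons), ncol = length(.REGIONS),
                dimnames = list(protons, .REGIONS))
  for (k in seq_len(nrow(table))) {
    reg <- regions[[table$surfactant_proton[k]]]
    out[table$solute_proton[k], reg] <-
      out[table$solute_proton[k], reg] +
      (if (weighted) table$intensity[k] else 1)
  }
  out
}

#' Radial localization score per solute proton
#'
#' For each solute proton the score is
#' `(n_core - n_surface) / (n_core + n_surface)` where core regions are
#' `chain` and `terminal_methyl` and surface regions are `spacer` and
#' `headgroup`. Scores above +1/3 are labelled `"core"`, below -1/3
#' `"surface"`, in between `"interface"`; protons without contacts are
#' `"unobserved"`. The +-1/3 label thresholds are a convention, not a
#' physical constant.
#'
#' @param summary A solute x region matrix from [region_summary()].
#' @return Data frame with `proton`, `score` (in `[-1, 1]`), and `label`.
#' @export
localization_index <- function(summary) {
  stopifnot(is.matrix(summary), all(.REGIONS %in% colnames(summary)))
  n_core <- rowSums(summary[, .CORE_REGIONS, drop = FALSE])
  n_surf <- rowSums(summary[, .SURFACE_REGIONS, drop = FALSE])
  tot <- n_core + n_surf
  score <- ifelse(tot > 0, (n_core - n_surf) / tot, NA_real_)
  label <- ifelse(tot == 0, "unobserved",
           ifelse(score > 1 / 3, "core",
           ifelse(score < -1 / 3, "surface", "interface")))
  data.frame(proton = rownames(summary), score = score, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Markdown report of a ROESY localization analysis
#'
#' @param table A `contact_table`.
#' @param regions A `region_map`.
#' @param file Optional path to write the Markdown report to.
#' @return The report lines, invisibly when written to file.
#' @export
roe_report <- function(table, regions = default_region_map(), file = NULL) {
  summ <- region_summary(table, regions)
  loc <- localization_index(summ)
  conc <- attr(table, "concentration_mM")
  lines <- c(
    "# ROESY contact localization summary", "",
    sprintf("- contacts: %d%s", nrow(table),
            if (!is.na(conc)) sprintf(" (surfactant %g mM)", conc) else ""),
    "",
    "| proton | chain | terminal_methyl | spacer | headgroup | score | label |",
    "|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(loc)), function(i) {
      p <- loc$proton[i]
      sprintf("| %s | %g | %g | %g | %g | %+.2f | %s |", p,
              summ[p, "chain"], summ[p, "terminal_methyl"],
              summ[p, "spacer"], summ[p, "headgroup"],
              loc$score[i], loc$label[i])
    }, character(1)))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
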