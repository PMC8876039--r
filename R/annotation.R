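#' @include AllClasses.R
NULL

.CLASS_ALIASES <- c(LYSOPC = "LPC", LYSOPE = "LPE", LYSOPG = "LPG")

#' Parse lipid shorthand names
#'
#' Parses names of the form \code{"<CLASS><C>:<D>"} in any of the common
#' dialects (\code{"PC34:2"}, \code{"PC 34:2"}, \code{"PC(34:2)"};
#' class token case-insensitive; \code{"LysoPC"} is accepted as an alias
#' for LPC, likewise LysoPE/LysoPG) into a species annotation table.
#' C is the total number of acyl carbons and D the total number of acyl
#' double bonds summed over the species' chains. Lyso classes carry one
#' acyl chain, all other classes two (diacylglycerol backbone).
#'
#' @param names character vector of lipid shorthand names
#' @return data.frame with columns \code{raw_name}, \code{name} (canonical
#'   \code{"CLASS C:D"} form), \code{head_class}, \code{total_carbons},
#'   \code{double_bonds}, \code{acyl_chains}
#' @examples
#' parseSpecies(c("PC 34:2", "LysoPC 18:1", "MGDG(36:6)"))
#' @export
parseSpecies <- function(names) {
  stopifnot(is.character(names), length(names) > 0L)
  m <- regmatches(names,
    regexec("^\\s*([A-Za-z]+)\\s*\\(?\\s*([^:()\\s]+):([^:()\\s]+)\\s*\\)?\\s*$",
            names, perl = TRUE))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("cannot parse lipid name(s): ",
         paste(sQuote(names[bad][seq_len(min(5, sum(bad)))]), collapse = ", "))
  tok <- toupper(vapply(m, `[`, "", 2L))
  tok <- ifelse(tok %in% names(.CLASS_ALIASES), .CLASS_ALIASES[tok], tok)
  unknown <- !(tok %in% LIPID_CLASSES)
  if (any(unknown))
    stop("unknown lipid class token(s): ",
         paste(sQuote(unique(vapply(m, `[`, "", 2L)[unknown])), collapse = ", "))
  cs <- vapply(m, `[`, "", 3L)
  ds <- vapply(m, `[`, "", 4L)
  okint <- function(x) grepl("^[0-9]+$", x)
  if (!all(okint(cs) & okint(ds)))
    stop("non-integer carbon or double-bond count in: ",
         paste(sQuote(names[!(okint(cs) & okint(ds))]), collapse = ", "))
  carbons <- as.integer(cs)
  db <- as.integer(ds)
  if (any(db > carbons))
    stop("double bonds exceed carbons in: ",
         paste(sQuote(names[db > carbons]), collapse = ", "))
  chains <- ifelse(tok %in% LYSO_CLASSES, 1L, 2L)
  data.frame(raw_name = names,
             name = sprintf("%s %d:%d", tok, carbons, db),
             head_class = tok,
             total_carbons = carbons,
             double_bonds = db,
             acyl_chains = chains,
             stringsAsFactors = FALSE)
}

#' Chain-length / double-bond grouping key
#'
#' Returns \code{"C:D"}, the key under which species from all head-group
#' classes with the same total chain length and number of double bonds are
#' summed (e.g. the 36:6, 38:4, 38:5, 38:6, 42:2 and 42:3 groups).
#'
#' @param annotation data.frame from \code{\link{parseSpecies}} (or the
#'   \code{rowData} of an annotated \linkS4class{LipidStudy})
#' @return character vector of group keys
#' @export
groupKey <- function(annotation) {
  sprintf("%d:%d", annotation$total_carbons, annotation$double_bonds)
}

#' Average number of double bonds per acyl chain
#'
#' The per-species unsaturation measure: total double bonds divided by the
#' number of acyl chains (2 for diacyl classes, 1 for lyso classes).
#'
#' @param annotation data.frame from \code{\link{parseSpecies}}
#' @return numeric vector
#' @export
avgDoubleBonds <- function(annotation) {
  annotation$double_bonds / annotation$acyl_chains
}

#' Export the species dictionary as TSV
#'
#' Writes columns \code{name}, \code{class}, \code{carbons},
#' \code{double_bonds}, \code{chains}.
#'
#' @param annotation data.frame from \code{\link{parseSpecies}}
#' @param path output file path
#' @export
writeSpeciesTable <- function(annotation, path) {
  out <- data.frame(name = annotation$name,
                    class = annotation$head_class,
                    carbons = annotation$total_carbons,
                    double_bonds = annotation$double_bonds,
                    chains = annotation$acyl_chains)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a LipidStudy
#'
#' @param amounts species x samples non-negative matrix with species
#'   rownames and sample-id colnames
#' @param samples data.frame with columns \code{sample_id}, \code{genotype},
#'   \code{treatment}, \code{replicate}, \code{is_qc}, \code{dry_weight_mg},
#'   \code{run_order}; rows are matched to \code{colnames(amounts)} by
#'   \code{sample_id}
#' @param annotate parse rownames into a species annotation (set FALSE for
#'   pseudo-analytes such as class totals)
#' @return a \linkS4class{LipidStudy}
#' @export
LipidStudy <- function(amounts, samples, annotate = TRUE) {
  stopifnot(is.matrix(amounts), !is.null(rownames(amounts)),
            !is.null(colnames(amounts)))
  if (!all(.SAMPLE_COLUMNS %in% colnames(samples)))
    stop("samples table must have columns: ",
         paste(.SAMPLE_COLUMNS, collapse = ", "))
  idx <- match(colnames(amounts), samples$sample_id)
  if (anyNA(idx))
    stop("samples table is missing sample_id(s): ",
         paste(setdiff(colnames(amounts), samples$sample_id), collapse = ", "))
  cd <- samples[idx, , drop = FALSE]
  rownames(cd) <- cd$sample_id
  cd$is_qc <- as.logical(cd$is_qc)
  rd <- if (annotate) {
    ann <- parseSpecies(rownames(amounts))
    DataFrame(ann, row.names = rownames(amounts))
  } else {
    DataFrame(row.names = rownames(amounts))
  }
  se <- SummarizedExperiment(assays = list(amounts = amounts),
                             colData = DataFrame(cd), rowData = rd)
  new("LipidStudy", se)
}
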