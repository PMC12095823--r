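## Media and environment construction: the four canonical
## richness x oxygen environments and carbon-source variants.

OXYGEN_ID <- "o2_e"
DEFAULT_CARBON <- "glc__D_e"
DEFAULT_COMPONENT_CONC <- 10   # mmol/L, the standard initial concentration

#' Construct a medium
#'
#' @param name medium name.
#' @param concentrations named numeric vector, pool metabolite id ->
#'   initial concentration (mmol/L, all >= 0).
#' @param oxygen_regime `"aerobic"` or `"anaerobic"`; anaerobic media have
#'   their oxygen concentration forced to 0.
#' @return object of class `medium`.
#' @export
medium <- function(name, concentrations,
                   oxygen_regime = c("aerobic", "anaerobic")) {
  oxygen_regime <- match.arg(oxygen_regime)
  if (any(concentrations < 0))
    stop("negative concentration for '",
         names(concentrations)[which(concentrations < 0)[1]], "'")
  if (oxygen_regime == "anaerobic") concentrations[OXYGEN_ID] <- 0
  structure(list(name = name, concentrations = concentrations,
                 oxygen_regime = oxygen_regime),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %s (%s): %d components\n", x$name, x$oxygen_regime,
              sum(x$concentrations > 0)))
  invisible(x)
}

#' Read a media component table
#'
#' TSV with columns `metabolite_id`, `concentration_mmol_per_L` and
#' optionally `richness` (`minimal` components are included in both media;
#' `rich` components only in the rich medium).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_media_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("metabolite_id", "concentration_mmol_per_L")
  if (!all(need %in% names(tab)))
    stop("media table must have columns ", paste(need, collapse = ", "))
  if (!"richness" %in% names(tab)) tab$richness <- "minimal"
  tab
}

#' Write a media component table
#'
#' @param table data.frame as returned by [read_media_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_media_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build one of the four canonical environments
#'
#' Environments are the cross of medium richness (`rich`, `minimal`) and
#' oxygen regime (`aerobic`, `anaerobic`).  Every listed component enters
#' at 10 mmol/L unless the table overrides it; aerobic environments add
#' oxygen at 10 mmol/L, anaerobic environments set it to 0.
#'
#' @param richness `"rich"` or `"minimal"`.
#' @param oxygen `"aerobic"` or `"anaerobic"`.
#' @param media_table data.frame with columns `metabolite_id`,
#'   `concentration_mmol_per_L`, `richness` (see [read_media_table()]).
#' @return a [medium()].
#' @export
build_environment <- function(richness = c("rich", "minimal"),
                              oxygen = c("aerobic", "anaerobic"),
                              media_table) {
  richness <- match.arg(richness)
  oxygen <- match.arg(oxygen)
  if (missing(media_table) || is.null(media_table) || nrow(media_table) == 0)
    stop("empty media table")
  keep <- if (richness == "rich") rep(TRUE, nrow(media_table)) else
    media_table$richness == "minimal"
  tab <- media_table[keep, , drop = FALSE]
  tab <- tab[order(tab$metabolite_id), , drop = FALSE]
  conc <- stats::setNames(tab$concentration_mmol_per_L, tab$metabolite_id)
  conc[is.na(conc)] <- DEFAULT_COMPONENT_CONC
  if (oxygen == "aerobic") conc[OXYGEN_ID] <- DEFAULT_COMPONENT_CONC
  medium(name = paste(oxygen, richness, sep = "-"),
         concentrations = conc, oxygen_regime = oxygen)
}

#' Replace the primary carbon source of a medium
#'
#' Removes the designated primary carbon source (default glucose,
#' `glc__D_e`) and adds the investigated carbon source at 10 mmol/L; all
#' other components are conserved exactly.
#'
#' @param medium a [medium()].
#' @param carbon_id pool metabolite id of the new carbon source.
#' @param primary_id id of the carbon source being replaced.
#' @return a new [medium()].
#' @export
swap_carbon_source <- function(medium, carbon_id,
                               primary_id = DEFAULT_CARBON) {
  conc <- medium$concentrations
  if (!primary_id %in% names(conc) || !(conc[primary_id] > 0))
    stop("medium '", medium$name, "' lacks the primary carbon source '",
         primary_id, "'")
  if (carbon_id == primary_id) return(medium)
  conc <- conc[names(conc) != primary_id]
  conc[carbon_id] <- DEFAULT_COMPONENT_CONC
  structure(list(name = paste0(medium$name, "+", carbon_id),
                 concentrations = conc,
                 oxygen_regime = medium$oxygen_regime),
            class = "medium")
}
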