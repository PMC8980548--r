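#' Default house dust mite molecule panel
#'
#' The eleven Dermatophagoides pteronyssinus (Der p) and D. farinae (Der f)
#' allergen molecules of a multiplex component-resolved HDM panel, in
#' canonical order. All ranking tie-breaks and profile labels in the package
#' refer to this order.
#'
#' @return Character vector of the 11 molecule identifiers.
#' @export
#' @examples
#' hdm_panel()
hdm_panel <- function() {
  c("Der f 1", "Der f 2", "Der p 1", "Der p 2", "Der p 5", "Der p 7",
    "Der p 10", "Der p 11", "Der p 20", "Der p 21", "Der p 23")
}

#' Validate a molecule panel
#'
#' A panel is an ordered character vector of unique, non-empty molecule
#' names. The order is canonical for the run: every downstream tie-break
#' (profile labels, priority decisions) uses it.
#'
#' @param panel Character vector of molecule names.
#' @return The panel, invisibly, after validation.
#' @export
validate_panel <- function(panel) {
  if (!is.character(panel) || length(panel) < 1L)
    stop("panel must be a non-empty character vector", call. = FALSE)
  if (anyNA(panel) || any(!nzchar(panel)))
    stop("panel contains empty or missing molecule names", call. = FALSE)
  if (anyDuplicated(panel))
    stop("panel contains duplicate molecule names: ",
         paste(unique(panel[duplicated(panel)]), collapse = ", "),
         call. = FALSE)
  invisible(panel)
}

#' Read a panel definition file
#'
#' One molecule name per line; blank lines and lines starting with `#`
#' are ignored. Used to override the default 11-molecule HDM panel.
#'
#' @param path Path to the panel definition file.
#' @return Character vector of molecule names in file order.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  validate_panel(lines)
  lines
}
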