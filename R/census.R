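#' Aquifer census
#'
#' Counts of aquifers by number of resident species. The number of species
#' recorded in an aquifer is taken to equal the number of niches it offers
#' (at most three; competitive exclusion keeps one species per niche), so the
#' census doubles as the niche structure of the region.
#'
#' @param a1,a2,a3 Non-negative integer counts of aquifers holding exactly
#'   one, two or three species.
#' @return An object of class `aquifer_census`: a list with elements
#'   `total` (A = a1 + a2 + a3) and `by_niche` (named vector `c("1","2","3")`).
#' @examples
#' aquifer_census(18, 16, 11)
#' @export
aquifer_census <- function(a1, a2, a3) {
  counts <- c(a1, a2, a3)
  if (length(counts) != 3L || anyNA(counts) || !is.numeric(counts))
    stop("a1, a2, a3 must be single non-negative numbers", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("census counts must be non-negative integers", call. = FALSE)
  counts <- as.integer(counts)
  structure(
    list(total = sum(counts), by_niche = stats::setNames(counts, as.character(1:3))),
    class = "aquifer_census"
  )
}

#' @export
print.aquifer_census <- function(x, ...) {
  cat("Aquifer census: A =", x$total, "aquifers\n")
  cat("  species per aquifer 1/2/3:", paste(x$by_niche, collapse = "/"), "\n")
  invisible(x)
}

#' Census of the Yilgarn calcrete aquifers
#'
#' The published survey of stygobitic diving beetles in the Yilgarn region of
#' Western Australia: 45 isolated calcrete aquifers holding one (18 aquifers),
#' two (16) or three (11) endemic species.
#'
#' @return An [aquifer_census()] with a1 = 18, a2 = 16, a3 = 11.
#' @export
yilgarn_census <- function() aquifer_census(18L, 16L, 11L)

#' Read an aquifer census from a per-aquifer table
#'
#' Aggregates a TSV with columns `aquifer_id` and `n_species` into an
#' [aquifer_census()].
#'
#' @param path Path to a tab-separated file with header columns
#'   `aquifer_id`, `n_species`.
#' @return An [aquifer_census()].
#' @export
read_census <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("aquifer_id", "n_species") %in% names(tab)))
    stop("census table needs columns 'aquifer_id' and 'n_species'", call. = FALSE)
  if (anyDuplicated(tab$aquifer_id))
    stop("duplicated aquifer_id in census table", call. = FALSE)
  n <- tab$n_species
  if (any(!n %in% 1:3))
    stop("n_species must be 1, 2 or 3 (at most three niches per aquifer)", call. = FALSE)
  aquifer_census(sum(n == 1L), sum(n == 2L), sum(n == 3L))
}

as_census <- function(x) {
  if (inherits(x, "aquifer_census")) return(x)
  stop("expected an 'aquifer_census' object", call. = FALSE)
}
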