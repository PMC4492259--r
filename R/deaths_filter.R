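# Death-certificate filtering: age and underlying-cause rules, then
# aggregation of surviving records to daily counts per grid cell.

#' Filter death records and aggregate to daily cell counts
#'
#' Keeps records of persons strictly older than 65 whose underlying cause
#' of death is natural.  External causes are dropped: for ICD revisions 8
#' and 9 these are E-codes E800 and above, for revision 10 the categories
#' V01 through Y89 -- except causes attributable to natural heat or cold,
#' which are retained (revisions 8/9: E900.0, E900.9, E901.0, E901.8,
#' E901.9; revision 10: X30 and X31, including their subdivisions).
#' Surviving records are attached to the grid cell containing their
#' commune centroid and aggregated to daily counts.
#'
#' @param records `data.frame` with columns `date`, `lon`, `lat`
#'   (commune centroid), `age`, `icd_rev` (8, 9 or 10) and `cause`.
#' @param grid A [build_grid()] object.
#' @param age_min Age cut-off; records with `age > age_min` are kept
#'   (default 65, strict).
#' @return `data.frame` of daily counts (`cell_id`, `date`, `deaths`) with
#'   attribute `filter_counts`, a named vector accounting for every input
#'   record (kept, dropped_age, dropped_external, rejected, outside_grid).
#' @export
filter_deaths <- function(records, grid, age_min = 65) {
  required <- c("date", "lon", "lat", "age", "icd_rev", "cause")
  if (!all(required %in% names(records)))
    stop("records must have columns: ", paste(required, collapse = ", "))
  rev <- records$icd_rev
  if (!all(rev %in% c(8L, 9L, 10L)))
    stop("unknown ICD revision: ", paste(unique(rev[!rev %in% 8:10]), collapse = ", "))

  cls <- classify_cause(records$cause, rev)
  bad <- cls == "unparseable"
  if (any(bad))
    warning(sum(bad), " record(s) with unparseable cause codes rejected")
  old_enough <- records$age > age_min
  natural <- cls %in% c("natural", "retained")
  keep <- old_enough & natural & !bad

  cell <- rep(NA_character_, nrow(records))
  cell[keep] <- assign_point(records$lon[keep], records$lat[keep], grid)
  inside <- keep & !is.na(cell)

  counts <- c(kept = sum(inside),
              dropped_age = sum(!old_enough),
              dropped_external = sum(old_enough & cls == "external"),
              rejected = sum(old_enough & bad),
              outside_grid = sum(keep & is.na(cell)))
  if (sum(counts) != nrow(records)) stop("internal accounting error")  # nocov

  if (!any(inside)) {
    out <- data.frame(cell_id = character(0), date = as.Date(character(0)),
                      deaths = integer(0))
  } else {
    agg <- stats::aggregate(
      list(deaths = rep(1L, sum(inside))),
      by = list(cell_id = cell[inside], date = as.Date(records$date[inside])),
      FUN = sum)
    out <- agg[order(agg$cell_id, agg$date), ]
    rownames(out) <- NULL
  }
  attr(out, "filter_counts") <- counts
  out
}

# One of "natural", "external", "retained", "unparseable" per record.
classify_cause <- function(cause, rev) {
  cause <- toupper(trimws(as.character(cause)))
  out <- character(length(cause))
  old <- rev %in% c(8L, 9L)

  # ICD-8/9: E-codes E800+ are external; named heat/cold codes retained.
  retained89 <- c("E900.0", "E900.9", "E901.0", "E901.8", "E901.9")
  is_ecode <- old & grepl("^E[0-9]{3}(\\.[0-9])?$", cause)
  enum <- suppressWarnings(as.integer(substr(cause, 2L, 4L)))
  out[old] <- "natural"
  out[is_ecode & enum >= 800L] <- "external"
  out[old & cause %in% retained89] <- "retained"
  ok89 <- grepl("^[A-Z]?[0-9]{3}(\\.[0-9]+)?$|^E[0-9]{3}(\\.[0-9])?$", cause)
  out[old & !ok89] <- "unparseable"

  # ICD-10: categories V01-Y89 external; X30/X31 retained.
  new <- rev == 10L
  ok10 <- grepl("^[A-Z][0-9]{2}(\\.[0-9]+)?$", cause)
  cat3 <- substr(cause, 1L, 3L)
  ext10 <- ok10 & cat3 >= "V01" & cat3 <= "Y89"
  out[new] <- "natural"
  out[new & ext10] <- "external"
  out[new & cat3 %in% c("X30", "X31")] <- "retained"
  out[new & !ok10] <- "unparseable"
  out
}
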