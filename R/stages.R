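#' Load a geological stage table
#'
#' Reads a stage dictionary with columns `stage`, `series`, `period`,
#' `max_ma`, `min_ma`, `international`. The packaged default covers the
#' Kasimovian through the Valanginian so that a Permian--Jurassic analysis
#' window can be buffered by two stages on either side against edge effects.
#'
#' @param path CSV path; `NULL` loads the packaged default table.
#' @return data frame ordered from oldest to youngest stage.
#' @export
#' @examples
#' stages <- load_stage_table()
#' head(stages)
load_stage_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stage_table.csv", package = "paleodiv")
  }
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("stage", "max_ma", "min_ma")
  if (!all(req %in% names(st))) {
    stop("stage table must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(st$international)) st$international <- TRUE
  st <- st[order(-st$max_ma), , drop = FALSE]
  if (any(diff(-st$max_ma) <= 0) || any(st$max_ma <= st$min_ma)) {
    stop("stage table intervals must be positive and non-overlapping")
  }
  rownames(st) <- NULL
  st
}

#' Split stages into early/late substages
#'
#' Each stage is divided equally into an early and a late half, the finest
#' temporal resolution used when censoring occurrence ages.
#'
#' @param stages stage table from [load_stage_table()].
#' @return data frame with columns `substage`, `stage`, `series`, `max_ma`,
#'   `min_ma`, `international`, oldest first.
#' @export
substage_table <- function(stages) {
  mid <- (stages$max_ma + stages$min_ma) / 2
  out <- data.frame(
    substage = c(rbind(paste("Early", stages$stage), paste("Late", stages$stage))),
    stage = rep(stages$stage, each = 2),
    series = if (is.null(stages$series)) NA_character_ else rep(stages$series, each = 2),
    max_ma = c(rbind(stages$max_ma, mid)),
    min_ma = c(rbind(mid, stages$min_ma)),
    international = rep(stages$international, each = 2),
    stringsAsFactors = FALSE
  )
  out[order(-out$max_ma), , drop = FALSE]
}

#' Stage or series boundary ages
#'
#' Returns the strictly decreasing vector of interval boundary ages at stage
#' or series resolution, used as preservation rate-shift times in the
#' time-variable Poisson model.
#'
#' @param stages stage table.
#' @param level `"stage"` or `"series"`.
#' @return numeric vector of ages (Ma), oldest first.
#' @export
stage_boundaries <- function(stages, level = c("stage", "series")) {
  level <- match.arg(level)
  if (level == "stage") {
    b <- c(stages$max_ma, stages$min_ma[nrow(stages)])
  } else {
    keep <- !duplicated(stages$series)
    b <- c(stages$max_ma[keep], stages$min_ma[nrow(stages)])
  }
  sort(unique(b), decreasing = TRUE)
}

# Row index of the interval containing each age under the half-open
# [older, younger) convention; the oldest interval is closed at its base.
# Errors naming the age when an age is not covered.
interval_index <- function(age, max_ma, min_ma) {
  idx <- rep(NA_integer_, length(age))
  for (i in seq_along(age)) {
    hit <- which(max_ma >= age[i] & age[i] > min_ma)
    if (length(hit) == 0L && length(max_ma) > 0L && age[i] == min_ma[which.min(min_ma)]) {
      hit <- which.min(min_ma)
    }
    if (length(hit) == 0L) {
      stop(sprintf("age %.4f Ma is not covered by the stage table", age[i]),
           call. = FALSE)
    }
    idx[i] <- hit[1L]
  }
  idx
}
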