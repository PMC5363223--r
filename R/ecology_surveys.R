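CORAL_STATUSES <- c("pigmented", "bleached", "recently_dead")

#' Photo-transect survey design arithmetic
#'
#' For a station surveyed with `n_transects` transects of
#' `transect_length_m` metres photographed every `photo_interval_m` metres,
#' with `points_per_photo` random points identified per image.
#'
#' @param n_transects,transect_length_m,photo_interval_m,points_per_photo
#'   Positive integers; the transect length must be divisible by the photo
#'   interval.
#' @return List with `photos_per_station` and `points_per_station`.
#' @export
survey_design <- function(n_transects, transect_length_m, photo_interval_m,
                          points_per_photo) {
  for (v in c(n_transects, transect_length_m, photo_interval_m, points_per_photo)) {
    if (!is.finite(v) || v <= 0 || v != round(v)) {
      stop_domain("all survey design arguments must be positive integers")
    }
  }
  if (transect_length_m %% photo_interval_m != 0) {
    stop_domain("transect length is not divisible by the photo interval")
  }
  photos <- n_transects * (transect_length_m / photo_interval_m)
  list(photos_per_station = photos,
       points_per_station = photos * points_per_photo)
}

check_points <- function(points) {
  need <- c("station", "phase", "photo_id", "point_index", "label", "status")
  miss <- setdiff(need, names(points))
  if (length(miss)) stop_domain("point table missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(points)) stop_domain("empty point table")
  bad <- !points$status %in% c(CORAL_STATUSES, "not_coral")
  if (any(bad)) stop_domain("unknown status: ", points$status[which(bad)[1]])
  invisible(TRUE)
}

#' Tabulate benthic cover from point counts
#'
#' Fraction of points per category (genus or substrate type), pooled over the
#' table or per station. Live-coral cover is the fraction of all points whose
#' status is `pigmented`.
#'
#' @param points Point-record data.frame with columns `station`, `phase`,
#'   `photo_id`, `point_index`, `label`, `status`.
#' @param pool_by `"all"` (one pooled summary) or `"station"`.
#' @return A data.frame of class `cover_summary` with columns `station`,
#'   `category`, `n`, `fraction`; `attr(, "live_cover")` holds a per-station
#'   data.frame of live-coral cover and point totals.
#' @export
tabulate_cover <- function(points, pool_by = c("all", "station")) {
  check_points(points)
  pool_by <- match.arg(pool_by)
  grp <- if (pool_by == "all") rep("all", nrow(points)) else as.character(points$station)
  pieces <- lapply(split(seq_len(nrow(points)), grp), function(idx) {
    tab <- table(points$label[idx])
    data.frame(station = grp[idx][1], category = names(tab),
               n = as.integer(tab), fraction = as.numeric(tab) / length(idx),
               row.names = NULL)
  })
  out <- do.call(rbind, c(pieces, make.row.names = FALSE))
  live <- vapply(split(seq_len(nrow(points)), grp), function(idx) {
    c(mean(points$status[idx] == "pigmented"), length(idx))
  }, numeric(2))
  attr(out, "live_cover") <- data.frame(station = colnames(live),
                                        live_cover = live[1, ],
                                        n_points = as.integer(live[2, ]),
                                        row.names = NULL)
  class(out) <- c("cover_summary", "data.frame")
  out
}

#' Live-coral cover from a cover summary
#'
#' @param summary A [tabulate_cover()] result.
#' @return Named numeric vector of live (pigmented) coral cover per station.
#' @export
live_coral_cover <- function(summary) {
  lc <- attr(summary, "live_cover")
  stats::setNames(lc$live_cover, lc$station)
}

#' Per-genus bleaching status fractions
#'
#' Over the coral points of each genus (status one of pigmented, bleached,
#' recently_dead), the three-way status split used to compare bleaching
#' susceptibility and mortality across genera. Genera with zero coral points
#' are omitted.
#'
#' @param points Point-record data.frame (see [tabulate_cover()]).
#' @return A data.frame with columns `genus`, `pigmented`, `bleached`,
#'   `recently_dead`, `n`; the three fractions sum to 1 per genus.
#' @export
genus_status_fractions <- function(points) {
  check_points(points)
  coral <- points[points$status %in% CORAL_STATUSES, ]
  if (!nrow(coral)) stop_domain("no coral points in table")
  pieces <- lapply(split(coral, as.character(coral$label)), function(d) {
    data.frame(genus = d$label[1],
               pigmented = mean(d$status == "pigmented"),
               bleached = mean(d$status == "bleached"),
               recently_dead = mean(d$status == "recently_dead"),
               n = nrow(d))
  })
  do.call(rbind, c(pieces, make.row.names = FALSE))
}

#' Compare pre- and post-event cover summaries
#'
#' Per-category absolute and relative change between two pooled cover
#' summaries, flagging categories whose cover at least halved.
#'
#' @param pre,post Pooled [tabulate_cover()] results over the same category
#'   universe (an error lists any mismatch).
#' @return A data.frame with columns `category`, `pre`, `post`, `change`,
#'   `rel_change_pct`, `halved`.
#' @export
compare_surveys <- function(pre, post) {
  d <- union(setdiff(pre$category, post$category), setdiff(post$category, pre$category))
  if (length(d)) {
    stop_domain("category universes differ: ", paste(sort(d), collapse = ", "))
  }
  m <- match(pre$category, post$category)
  out <- data.frame(category = pre$category, pre = pre$fraction,
                    post = post$fraction[m])
  out$change <- out$post - out$pre
  out$rel_change_pct <- 100 * out$change / out$pre
  out$halved <- out$post <= 0.5 * out$pre
  out[order(out$category), , drop = FALSE]
}
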