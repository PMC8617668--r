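#' Group overlapping detections from several models
#'
#' When k independently trained models run on the same frame, each real
#' object typically attracts one box from several of them. This clusters the
#' pooled detections greedily: sort by descending confidence; the top
#' unassigned detection seeds a group, which then absorbs, from every
#' *other* model, its best-overlapping unassigned detection with IoU to the
#' seed at or above `group_iou` (at most one member per model, so no model
#' can double-vote in a group); repeat until all detections are assigned.
#' Grouping is done per frame.
#'
#' @param dets Pooled detection tibble; `source_id` identifies the model.
#' @param group_iou IoU to the seed required to join a group; default 0.5.
#' @return The detections with an added integer `group` column; groups are
#'   numbered in seed order across the whole table.
#' @export
group_detections <- function(dets, group_iou = 0.5) {
  validate_detections(dets)
  stopifnot(group_iou > 0, group_iou <= 1)
  if (nrow(dets) == 0) return(dplyr::mutate(dets, group = integer(0)))
  dets$group <- NA_integer_
  next_id <- 1L
  for (d in split(seq_len(nrow(dets)), dets$frame)) {
    sub <- dets[d, , drop = FALSE]
    ord <- d[order(-sub$confidence)]
    assigned <- rep(FALSE, nrow(dets))
    for (i in ord) {
      if (assigned[i]) next
      dets$group[i] <- next_id
      assigned[i] <- TRUE
      cand <- ord[!assigned[ord] & dets$source_id[ord] != dets$source_id[i]]
      if (length(cand) > 0) {
        ious <- iou_matrix(dets[i, ], dets[cand, , drop = FALSE])[1, ]
        ok <- cand[ious >= group_iou]
        if (length(ok) > 0) {
          # at most one member per model: take the best-IoU candidate,
          # ties falling to the higher-confidence (earlier-sorted) one
          best <- vapply(split(ok, dets$source_id[ok]), function(idx) {
            io <- ious[match(idx, cand)]
            idx[order(-io, match(idx, ord))][1]
          }, integer(1))
          dets$group[best] <- next_id
          assigned[best] <- TRUE
        }
      }
      next_id <- next_id + 1L
    }
  }
  dets
}

#' Vote grouped detections into an ensemble output
#'
#' Applies one of three voting strategies to the groups produced by
#' [group_detections()]: *affirmative* keeps a group if any model
#' contributed (vote count >= 1), *consensus* if a strict majority did
#' (vote count > k/2, i.e. at least 4 of 6), *unanimous* only if all k
#' models did. Each kept group is emitted as its highest-confidence member's
#' box with confidence replaced by the mean over members.
#'
#' @param grouped Output of [group_detections()].
#' @param strategy `"affirmative"`, `"consensus"` or `"unanimous"`.
#' @param k Number of models in the ensemble; defaults to the number of
#'   distinct `source_id`s present.
#' @return A detection tibble with `source_id` set to
#'   `"ensemble:<strategy>"` and an added `votes` column.
#' @export
vote_detections <- function(grouped,
                            strategy = c("affirmative", "consensus",
                                         "unanimous"),
                            k = dplyr::n_distinct(grouped$source_id)) {
  strategy <- match.arg(strategy)
  if (!"group" %in% names(grouped)) {
    rlang::abort("input must come from group_detections() (no group column)")
  }
  stopifnot(k >= 1)
  if (nrow(grouped) == 0) {
    return(dplyr::mutate(grouped[0, ], votes = integer(0)))
  }
  need <- switch(strategy, affirmative = 1, consensus = floor(k / 2) + 1,
                 unanimous = k)
  out <- grouped |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      frame = .data$frame[1],
      votes = dplyr::n_distinct(.data$source_id),
      mean_conf = mean(.data$confidence),
      x = .data$x[which.max(.data$confidence)],
      y = .data$y[which.max(.data$confidence)],
      w = .data$w[which.max(.data$confidence)],
      h = .data$h[which.max(.data$confidence)],
      .groups = "drop") |>
    dplyr::filter(.data$votes >= need) |>
    dplyr::arrange(.data$group)
  detections(x = out$x, y = out$y, w = out$w, h = out$h,
             confidence = out$mean_conf, frame = out$frame,
             source_id = paste0("ensemble:", strategy)) |>
    dplyr::mutate(votes = out$votes)
}

#' One-call ensemble: group then vote
#'
#' @inheritParams group_detections
#' @inheritParams vote_detections
#' @return A detection tibble (see [vote_detections()]).
#' @examples
#' d <- dplyr::bind_rows(
#'   detections(10, 10, 20, 20, 0.9, source_id = "m1"),
#'   detections(11, 10, 20, 20, 0.8, source_id = "m2"))
#' ensemble_detections(d, "affirmative", k = 2)
#' @export
ensemble_detections <- function(dets,
                                strategy = c("affirmative", "consensus",
                                             "unanimous"),
                                k = dplyr::n_distinct(dets$source_id),
                                group_iou = 0.5) {
  vote_detections(group_detections(dets, group_iou), strategy, k)
}
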