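# Axial mosaic of a volume as a grayscale image matrix in [0,1], with an
# optional display threshold (|t| below it rendered as background).
axial_mosaic <- function(volume, n_slices = 9L, threshold = 0) {
  shape <- volume$shape
  zs <- unique(round(seq(1, shape[3], length.out = n_slices)))
  vals <- volume$values
  if (threshold > 0) vals[abs(vals) < threshold] <- 0
  rng <- range(vals)
  if (diff(rng) == 0) rng <- c(rng[1], rng[1] + 1)
  ncol_t <- ceiling(sqrt(length(zs)))
  nrow_t <- ceiling(length(zs) / ncol_t)
  mos <- matrix(0, nrow = nrow_t * shape[2], ncol = ncol_t * shape[1])
  for (i in seq_along(zs)) {
    r <- (i - 1) %/% ncol_t
    c <- (i - 1) %% ncol_t
    sl <- (vals[, , zs[i]] - rng[1]) / diff(rng)
    # flip the y axis so anterior is up in image coordinates
    mos[r * shape[2] + seq_len(shape[2]),
        c * shape[1] + seq_len(shape[1])] <- t(sl[, shape[2]:1])
  }
  mos
}

mosaic_png_b64 <- function(volume, threshold = 0) {
  raw <- png::writePNG(axial_mosaic(volume, threshold = threshold))
  jsonlite::base64_enc(raw)
}

#' Write an ordered, labeled classification report
#'
#' Renders the classified components of (typically) one subject as an
#' ordered HTML report — components grouped by predicted network in the
#' fixed network order, ascending component index within a network, one
#' axial mosaic per component — plus a machine-readable TSV of
#' (subject, component, predicted label, score).
#'
#' @param components list of [component_map()]s.
#' @param predictions data.frame with columns `subject`, `component`,
#'   `label`, and optionally `score`; every component needs a row.
#' @param out_path output HTML path; the TSV is written alongside with
#'   extension `.tsv`.
#' @param threshold display threshold on |t| for the mosaics only
#'   (classification always uses unthresholded maps); default 0.
#' @param label_set network ordering for the sections.
#' @return Invisible character vector of the HTML and TSV paths.
#' @export
write_labeled_report <- function(components, predictions, out_path,
                                 threshold = 0,
                                 label_set = network_labels()) {
  stopifnot(is.data.frame(predictions),
            all(c("subject", "component", "label") %in% names(predictions)))
  if (!"score" %in% names(predictions)) predictions$score <- NA_real_
  key <- function(s, c) paste(s, c, sep = ":")
  pk <- key(predictions$subject, predictions$component)
  ck <- vapply(components, function(cm)
    key(cm$subject_id, cm$component_index), "")
  missing <- setdiff(ck, pk)
  if (length(missing))
    stop("missing prediction for component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  rows <- predictions[match(ck, pk), ]
  ord <- order(match(rows$label, label_set),
               rows$subject, rows$component)
  rows <- rows[ord, ]
  comps <- components[ord]

  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>Resting-state network labeling report</title>",
            "<style>body{font-family:sans-serif;max-width:60em;margin:auto}",
            "img{image-rendering:pixelated;width:100%;",
            "background:#000}</style></head><body>",
            "<h1>Resting-state network labeling report</h1>",
            sprintf("<p>%d component(s); display threshold |t| &ge; %g.</p>",
                    length(comps), threshold))
  for (lb in label_set) {
    html <- c(html, sprintf("<h2>%s</h2>", gsub("_", " ", lb)))
    in_net <- which(rows$label == lb)
    if (!length(in_net)) {
      html <- c(html, "<p><em>no components</em></p>")
      next
    }
    for (i in in_net) {
      cm <- comps[[i]]
      html <- c(html,
        sprintf("<h3>subject %s &mdash; IC %d (score %s)</h3>",
                cm$subject_id, cm$component_index,
                ifelse(is.na(rows$score[i]), "n/a",
                       signif(rows$score[i], 3))),
        sprintf("<img alt='IC %d mosaic' src='data:image/png;base64,%s'/>",
                cm$component_index,
                mosaic_png_b64(cm$volume, threshold = threshold)))
    }
  }
  html <- c(html, "</body></html>")
  writeLines(html, out_path)

  tsv_path <- paste0(tools::file_path_sans_ext(out_path), ".tsv")
  utils::write.table(
    data.frame(subject = rows$subject, component = rows$component,
               predicted_label = rows$label, score = rows$score),
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(out_path, tsv_path))
}
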