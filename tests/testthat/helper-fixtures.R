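# in-code fixtures shared across test files

# hard-edged disk field (no anti-aliasing): exact-oracle segmentation inputs.
# disks: list of list(x, y, r (px), value, channel)
disk_field <- function(disks, H = 120, W = 160, pixel_scale = 0.65,
                       channels = c("hoechst", "ch488")) {
  chans <- setNames(lapply(channels, function(ch) matrix(0, H, W)), channels)
  for (d in disks) {
    ch <- d$channel %||% "hoechst"
    rows <- matrix(rep(seq_len(H), W), H, W)
    cols <- matrix(rep(seq_len(W), each = H), H, W)
    inside <- (rows - d$y)^2 + (cols - d$x)^2 < d$r^2
    chans[[ch]][inside] <- chans[[ch]][inside] + d$value
  }
  field_image(chans, pixel_scale = pixel_scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# greedy bipartite centroid matching within tol_um; returns precision/recall
match_detections <- function(truth_xy, cand_xy, tol_um = 2) {
  nt <- nrow(truth_xy); nc <- nrow(cand_xy)
  if (nt == 0 || nc == 0)
    return(list(matched = 0, precision = ifelse(nc == 0, 1, 0),
                recall = ifelse(nt == 0, 1, 0)))
  D <- sqrt(outer(truth_xy[[1]], cand_xy[[1]], "-")^2 +
            outer(truth_xy[[2]], cand_xy[[2]], "-")^2)
  used <- rep(FALSE, nc); matched <- 0
  for (i in order(apply(D, 1, min))) {
    j <- which.min(ifelse(used, Inf, D[i, ]))
    if (is.finite(D[i, j]) && D[i, j] <= tol_um) {
      matched <- matched + 1; used[j] <- TRUE
    }
  }
  list(matched = matched, precision = matched / nc, recall = matched / nt)
}

# candidate centroids in um from a find_nuclei() table
candidate_xy_um <- function(nuc, pixel_scale = 0.65) {
  data.frame(x = (nuc$x_px + 0.5) * pixel_scale,
             y = (nuc$y_px + 0.5) * pixel_scale)
}

# canonical relabelling by raster order (column-major first pixel) so two
# label matrices can be compared irrespective of original label ids
canonical_labels <- function(labels) {
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  first <- vapply(ids, function(id) min(which(labels == id)), integer(1))
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (k in seq_along(ids)) out[labels == ids[order(first)][k]] <- k
  out
}

# delta-method SE of a pooled-count ratio R = X/Y with multinomial (n, p1, p2)
ratio_delta_se <- function(n, p1, p2) {
  (p1 / p2) * sqrt((1 - p1) / (n * p1) + (1 - p2) / (n * p2) + 2 / n)
}

# a classified-nucleus table with fixed subtype counts
make_classified <- function(well, n_co, n_so, n_dual, n_un) {
  lv <- c("ctip2_only", "satb2_only", "dual", "unlabeled")
  tibble::tibble(
    well = well,
    subtype_ctip2_satb2 = factor(rep(lv, c(n_co, n_so, n_dual, n_un)), levels = lv))
}

# textbook pooled-variance two-sample t statistic (independent oracle)
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
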