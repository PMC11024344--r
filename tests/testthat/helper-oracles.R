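# Independent brute-force oracles and small fixture builders.

# Exhaustive nearest-vessel-pixel Euclidean distance (pixel centres), in um.
bf_distance_field <- function(mask, pixel_size_um = 1) {
  idx <- which(mask, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(Inf, nr, nc)
  if (nrow(idx) == 0) return(out)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      out[r, cc] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - cc)^2))
    }
  }
  out * pixel_size_um
}

# Exhaustive 4-connected component count with a size filter (pixel units).
bf_count_components <- function(bin, min_px = 0) {
  nr <- nrow(bin); nc <- ncol(bin)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (!bin[r0, c0] || seen[r0, c0]) next
      stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0L
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              bin[q[1], q[2]] && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
      if (size >= min_px) count <- count + 1L
    }
  }
  count
}

# A one-channel ImageStack from a plain matrix.
mat_image <- function(m, pixel_size_um = 1, channel = "ch1") {
  image_stack(m, channel, pixel_size_um)
}

# Horizontal straight tube plus isolated dots, as a CD31-like intensity
# image: the tube passes the elongation filter, the dots do not.
tube_and_dots_image <- function(nr = 60, nc = 120, pixel_size_um = 1) {
  x <- matrix(0.02, nr, nc)
  x[28:32, 10:110] <- 0.9            # 5 x 101 px tube, axis ratio >> 2.5
  for (p in list(c(10, 20), c(12, 80), c(50, 40), c(48, 100))) {
    x[p[1]:(p[1] + 1), p[2]:(p[2] + 1)] <- 0.9   # 2x2 punctate dots
  }
  mat_image(x, pixel_size_um, "CD31")
}

# Offsets table used across recovery tests.
offsets_table <- function(rgl_kd, ipc_kd, rgl_wt = 2.5, ipc_wt = -1.6,
                          groups = c("WT", "KD")) {
  data.frame(phenotype = rep(c("RGL-NSC", "IPC"), each = 2),
             group = rep(groups, 2),
             offset_um = c(rgl_wt, rgl_wt + rgl_kd, ipc_wt, ipc_wt + ipc_kd))
}

# Difference of group means of per-animal mean distances, and its SEM,
# from a run_pipeline() per-animal table.
group_diff_sem <- function(per_animal, phen, groups) {
  s <- per_animal[per_animal$phenotype == phen, ]
  gm <- tapply(s$mean_dist_um, s$group, mean)
  v <- tapply(s$mean_dist_um, s$group, var)
  n <- table(s$group)
  list(diff = unname(gm[groups[2]] - gm[groups[1]]),
       sem = sqrt(sum(v[groups] / n[groups])))
}
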