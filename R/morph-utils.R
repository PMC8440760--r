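## Shared low-level morphology helpers.

## 8-connected labelling built on EBImage's 4-connected bwlabel by
## merging components that touch diagonally (union-find over label ids).
label8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  nl <- max(lab)
  if (nl <= 1) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # \ diagonal
    cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W]))    # / diagonal
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

## Summarise a label matrix into one row per component.
label_stats <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    return(tibble(label = integer(), area = integer(),
                  row0 = integer(), col0 = integer(),
                  row1 = integer(), col1 = integer(),
                  centroid_row = numeric(), centroid_col = numeric()))
  }
  rr <- ((idx - 1) %% nrow(lab)) + 1
  cc <- ((idx - 1) %/% nrow(lab)) + 1
  ll <- lab[idx]
  df <- tibble(label = ll, r = rr, c = cc)
  dplyr::summarise(dplyr::group_by(df, .data$label),
                   area = dplyr::n(),
                   row0 = min(.data$r), col0 = min(.data$c),
                   row1 = max(.data$r), col1 = max(.data$c),
                   centroid_row = mean(.data$r), centroid_col = mean(.data$c),
                   .groups = "drop")
}

disc_brush <- function(radius) {
  size <- 2L * as.integer(ceiling(radius)) + 1L
  EBImage::makeBrush(size, shape = "disc")
}
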