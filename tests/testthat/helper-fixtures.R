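# regular k x k grid filling a square window (spacing = side / k)
grid_field <- function(k, side = 1000) {
  step <- side / k
  centres <- step / 2 + step * (0:(k - 1))
  g <- expand.grid(x = centres, y = centres)
  point_field(g$x, g$y, window = c(0, 0, side, side))
}

# hexagon of radius r around a centre point
hex_field <- function(r = 200, centre = c(500, 500),
                      window = c(0, 0, 1000, 1000)) {
  th <- 2 * pi * (0:5) / 6
  point_field(c(centre[1] + r * cos(th), centre[1]),
              c(centre[2] + r * sin(th), centre[2]),
              window = window)
}

# binary image with k planted square dots (dot_px x dot_px) whose centres are
# pairwise separated by more than `sep` pixels; returns matrix + true centroids
planted_dot_image <- function(seed, k, side_px = 500, dot_px = 2, sep = 6) {
  set.seed(seed)
  img <- matrix(0, side_px, side_px)
  cx <- numeric(0)
  cy <- numeric(0)
  tries <- 0
  while (length(cx) < k) {
    px <- sample(seq(dot_px + 2, side_px - dot_px - 2), 1)
    py <- sample(seq(dot_px + 2, side_px - dot_px - 2), 1)
    if (length(cx) == 0 || all((cx - px)^2 + (cy - py)^2 > sep^2)) {
      cx <- c(cx, px)
      cy <- c(cy, py)
    }
    tries <- tries + 1
    if (tries > 1e5) stop("could not plant dots")
  }
  for (i in seq_len(k)) {
    rows <- cy[i]:(cy[i] + dot_px - 1)  # matrix rows (top-down)
    cols <- cx[i]:(cx[i] + dot_px - 1)
    img[rows, cols] <- 1
  }
  # true centroid of the dot_px x dot_px block, in bottom-left um coordinates
  true_x <- cx - 0.5 + (dot_px - 1) / 2
  true_y <- side_px - (cy - 0.5 + (dot_px - 1) / 2)
  list(image = img, x = true_x, y = true_y)
}

write_coords_csv <- function(df, path, sep = ",", header = TRUE) {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = header)
  path
}
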