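## Spatial substrate: tri-state site grid, direction algebra, track
## initialization. Coordinates are 0-based; x grows distally.

## Site states share the integer codes used by the compiled engine.
SITE_CLOSED <- 0L
SITE_OPEN <- 1L
SITE_OCCUPIED <- 2L

.direction_names <- c(
  "distal", "distal_anterior", "anterior", "proximal_anterior",
  "proximal", "proximal_posterior", "posterior", "distal_posterior", "none"
)
.direction_dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L, 0L)
.direction_dy <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L, 0L)

#' Compass directions on the migration lattice
#'
#' Agents move in one of eight compass directions or not at all (`"none"`).
#' `"distal"` is +x (towards the migratory target at the far edge of the
#' grid), `"proximal"` is -x, and `"anterior"`/`"posterior"` are -y/+y.
#'
#' @return A data frame with one row per admissible direction value and
#'   columns `direction`, `dx`, `dy`. `"none"` has a zero offset but is never
#'   a movement direction.
#' @examples
#' directions()
#' @export
directions <- function() {
  data.frame(
    direction = .direction_names,
    dx = .direction_dx,
    dy = .direction_dy,
    stringsAsFactors = FALSE
  )
}

#' Offset of a compass direction
#'
#' @param direction A direction name (see [directions()]); `"none"` is not
#'   admissible here because it never maps to a coordinate offset.
#' @return Integer vector `c(dx, dy)`.
#' @export
direction_offset <- function(direction) {
  i <- match(direction, .direction_names)
  if (is.na(i)) stop("unknown direction: ", direction)
  if (direction == "none") stop("'none' has no coordinate offset")
  c(.direction_dx[i], .direction_dy[i])
}

#' Neighbouring site in a given direction
#'
#' The grid is non-cyclic: a step over the edge has no destination and `NULL`
#' is returned.
#'
#' @param pos Integer vector `c(x, y)`, 0-based.
#' @param direction A direction name other than `"none"` (a `"none"` draw
#'   means no movement decision was made, so asking for its neighbour is a
#'   caller error).
#' @param width,height Grid dimensions in sites.
#' @return `c(x, y)` of the adjacent site, or `NULL` if it lies off the grid.
#' @examples
#' neighbor_site(c(10, 10), "distal")          # c(11, 10)
#' neighbor_site(c(149, 10), "distal")         # NULL: non-cyclic boundary
#' @export
neighbor_site <- function(pos, direction, width = 150L, height = 45L) {
  off <- direction_offset(direction)
  dest <- c(pos[1] + off[1], pos[2] + off[2])
  if (dest[1] < 0 || dest[1] >= width || dest[2] < 0 || dest[2] >= height) {
    return(NULL)
  }
  dest
}

#' Create an all-Closed migration grid
#'
#' Sites start Closed (never yet occupied); an agent's wake turns them Open,
#' and a site never returns to Closed. Each site is 30 um across, roughly one
#' cell length, so the default 150 x 45 grid spans 4.5 mm x 1.35 mm.
#'
#' @param width,height Grid dimensions in sites.
#' @param site_width_um Physical edge length of one site, in micrometres.
#' @return A `migration_grid` object.
#' @export
new_grid <- function(width = 150L, height = 45L, site_width_um = 30) {
  if (width < 2 || height < 1) stop("grid must be at least 2 x 1 sites")
  structure(
    list(
      width = as.integer(width),
      height = as.integer(height),
      site_width_um = site_width_um,
      states = matrix(SITE_CLOSED, nrow = width, ncol = height)
    ),
    class = "migration_grid"
  )
}

#' @export
print.migration_grid <- function(x, ...) {
  tab <- table(factor(x$states, levels = 0:2,
                      labels = c("closed", "open", "occupied")))
  cat(sprintf(
    "<migration_grid> %d x %d sites (%.0f um/site): %d closed, %d open, %d occupied\n",
    x$width, x$height, x$site_width_um, tab[["closed"]], tab[["open"]],
    tab[["occupied"]]
  ))
  invisible(x)
}

.grid_get <- function(grid, pos) grid$states[pos[1] + 1L, pos[2] + 1L]
.grid_set <- function(grid, pos, state) {
  grid$states[pos[1] + 1L, pos[2] + 1L] <- state
  grid
}

#' Initialize a pre-existing track of Open sites
#'
#' A track models a path of least resistance presumed forged by preceding
#' cells: every site in the chain's row between the front agent and the
#' distal edge starts Open.
#'
#' @param grid A `migration_grid`, freshly created (all Closed except agent
#'   sites).
#' @param chain_row y index (0-based) of the chain's row.
#' @param front_x x index of the distal-most agent; sites `front_x + 1` to
#'   `width - 1` in `chain_row` are opened.
#' @return The updated grid.
#' @examples
#' g <- init_track(new_grid(), chain_row = 22, front_x = 8)
#' sum(g$states == 1)  # 141 open sites
#' @export
init_track <- function(grid, chain_row, front_x) {
  stopifnot(inherits(grid, "migration_grid"))
  if (front_x >= grid$width - 1L) {
    stop("degenerate track: front agent already at the distal edge")
  }
  for (x in seq.int(front_x + 1L, grid$width - 1L)) {
    grid <- .grid_set(grid, c(x, chain_row), SITE_OPEN)
  }
  grid
}

#' Apply an agent move to the grid
#'
#' The vacated site becomes Open (the agent's wake) and the destination
#' Occupied. Legal destinations are Open or Closed sites adjacent to the
#' agent, or the second site of a straight two-step move through Open sites
#' (the ATS rule); a move onto an Occupied or off-grid site indicates a bug
#' in the calling rule engine and is an error.
#'
#' @param grid A `migration_grid`.
#' @param from,to Integer `c(x, y)` positions, 0-based.
#' @return The updated grid.
#' @export
apply_move <- function(grid, from, to) {
  stopifnot(inherits(grid, "migration_grid"))
  if (to[1] < 0 || to[1] >= grid$width || to[2] < 0 || to[2] >= grid$height) {
    stop("move destination off the grid")
  }
  if (.grid_get(grid, from) != SITE_OCCUPIED) {
    stop("move origin is not occupied")
  }
  if (.grid_get(grid, to) == SITE_OCCUPIED) {
    stop("move destination is occupied")
  }
  d <- abs(to - from)
  straight_two <- (max(d) == 2L) && (to[1] - from[1]) %% 2L == 0L &&
    (to[2] - from[2]) %% 2L == 0L &&
    (d[1] == 0L || d[1] == 2L) && (d[2] == 0L || d[2] == 2L)
  if (max(d) > 1L && !straight_two) stop("destination not reachable in one move")
  grid <- .grid_set(grid, from, SITE_OPEN)
  if (straight_two) {  # the intermediate site of an ATS double step
    mid <- from + (to - from) %/% 2L
    if (.grid_get(grid, mid) != SITE_OPEN) stop("two-step move through a non-open site")
  }
  .grid_set(grid, to, SITE_OCCUPIED)
}

#' Serialize a grid to a plain-text raster
#'
#' One character per site: `#` Closed, `.` Open, `O` Occupied; one text line
#' per row (y), x increasing left to right. [read_grid_raster()] restores the
#' grid, so snapshots round-trip for replay and debugging.
#'
#' @param grid A `migration_grid`.
#' @param path File to write; omit to return the lines invisibly.
#' @return Character vector of raster lines, invisibly.
#' @export
write_grid_raster <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "migration_grid"))
  chars <- c("#", ".", "O")
  lines <- apply(grid$states, 2, function(col) paste(chars[col + 1L], collapse = ""))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a plain-text grid raster
#'
#' @param path File written by [write_grid_raster()], or a character vector
#'   of raster lines.
#' @param site_width_um Physical site size to record on the restored grid.
#' @return A `migration_grid`.
#' @export
read_grid_raster <- function(path, site_width_um = 30) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  height <- length(lines)
  width <- nchar(lines[1])
  if (any(nchar(lines) != width)) stop("ragged raster lines")
  codes <- c("#" = SITE_CLOSED, "." = SITE_OPEN, "O" = SITE_OCCUPIED,
             "L" = SITE_OCCUPIED, "F" = SITE_OCCUPIED)
  grid <- new_grid(width, height, site_width_um)
  for (y in seq_len(height)) {
    ch <- strsplit(lines[y], "")[[1]]
    bad <- !ch %in% names(codes)
    if (any(bad)) stop("unknown raster character: ", ch[bad][1])
    grid$states[, y] <- unname(codes[ch])
  }
  grid
}
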