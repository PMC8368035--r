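#' Construct and validate a plate layout
#'
#' A plate layout maps wells of a (by default 384-well, 16 x 24) plate to
#' experimental roles: library compound, vehicle (DMSO) control, positive
#' control, or empty.
#'
#' @param plate_id plate identifier.
#' @param row letter row labels (A-P for 384-well).
#' @param col integer column indices (1-24 for 384-well).
#' @param role one of `"compound"`, `"vehicle_control"`, `"positive_control"`,
#'   `"empty"` per well.
#' @param compound_id compound identifier (`NA` for controls/empty wells).
#' @param concentration_M molar concentration (`NA` where not applicable).
#' @param replicate integer replicate index.
#' @param geometry plate geometry as `c(rows, cols)`.
#' @return a `data.frame` of class `opl_layout` with one row per well and a
#'   `well` column (`"A01"` style).
#' @examples
#' plate_layout("demo", row = c("A", "A"), col = 1:2,
#'              role = c("vehicle_control", "positive_control"))
#' @export
plate_layout <- function(plate_id, row, col, role,
                         compound_id = NA_character_,
                         concentration_M = NA_real_,
                         replicate = 1L,
                         geometry = c(16L, 24L)) {
  roles <- c("compound", "vehicle_control", "positive_control", "empty")
  layout <- data.frame(
    plate_id = as.character(plate_id),
    row = toupper(as.character(row)),
    col = as.integer(col),
    role = as.character(role),
    compound_id = as.character(compound_id),
    concentration_M = as.numeric(concentration_M),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  layout$well <- sprintf("%s%02d", layout$row, layout$col)
  bad_role <- setdiff(unique(layout$role), roles)
  if (length(bad_role))
    stop("unknown well role(s): ", paste(bad_role, collapse = ", "))
  if (anyDuplicated(layout[c("plate_id", "well")]))
    stop("duplicate wells in layout: ",
         paste(layout$well[duplicated(layout[c("plate_id", "well")])],
               collapse = ", "))
  row_idx <- match(layout$row, LETTERS)
  if (any(is.na(row_idx)) || any(row_idx > geometry[1]) ||
      any(layout$col < 1) || any(layout$col > geometry[2]))
    stop("well coordinates outside ", geometry[1], "x", geometry[2],
         " plate geometry")
  if (any(!is.na(layout$concentration_M) & layout$concentration_M <= 0))
    stop("concentration_M must be positive when present")
  attr(layout, "geometry") <- as.integer(geometry)
  class(layout) <- c("opl_layout", "data.frame")
  layout
}

all_wells <- function(geometry = c(16L, 24L)) {
  expand.grid(row = LETTERS[seq_len(geometry[1])],
              col = seq_len(geometry[2]),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' The "90/10" assay-validation layout
#'
#' A 384-well plate with 320 vehicle (DMSO) wells and 32 positive-control
#' (Torin1) wells, the design used to estimate the screening window (Z')
#' before a full screen; the remaining 32 wells are empty.
#'
#' @param plate_id plate identifier.
#' @return an [plate_layout()] object.
#' @export
layout_90_10 <- function(plate_id = "90-10") {
  wells <- all_wells()
  wells <- wells[order(wells$col, wells$row), ]
  role <- c(rep("vehicle_control", 320), rep("positive_control", 32),
            rep("empty", 32))
  plate_layout(plate_id, wells$row, wells$col, role)
}

#' A screening plate layout for a compound batch
#'
#' Places up to 352 compounds on a 384-well plate with `n_dmso` vehicle wells
#' and `n_pos` positive-control wells; unused wells are marked empty.
#'
#' @param plate_id plate identifier.
#' @param compound_ids character vector of compound ids (length <= 384 -
#'   `n_dmso` - `n_pos`).
#' @param n_dmso number of DMSO wells (>= 8, enforced downstream).
#' @param n_pos number of positive-control wells.
#' @return an [plate_layout()] object.
#' @export
layout_screen <- function(plate_id, compound_ids, n_dmso = 24L, n_pos = 8L) {
  wells <- all_wells()
  wells <- wells[order(wells$col, wells$row), ]
  n_cpd <- length(compound_ids)
  if (n_cpd + n_dmso + n_pos > nrow(wells))
    stop("too many wells requested for a 384-well plate")
  role <- c(rep("vehicle_control", n_dmso), rep("positive_control", n_pos),
            rep("compound", n_cpd),
            rep("empty", nrow(wells) - n_dmso - n_pos - n_cpd))
  compound_id <- c(rep(NA_character_, n_dmso + n_pos), compound_ids,
                   rep(NA_character_, nrow(wells) - n_dmso - n_pos - n_cpd))
  plate_layout(plate_id, wells$row, wells$col, role, compound_id)
}

#' Read a plate map from CSV
#'
#' Expects columns `plate_id,row,col,role,compound_id,concentration_M,
#' replicate`. Malformed rows (duplicate wells, bad roles, coordinates off
#' the plate) are rejected with the offending line numbers.
#'
#' @param path CSV file path.
#' @return an [plate_layout()] object.
#' @export
read_plate_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("plate_id", "row", "col", "role", "compound_id",
                "concentration_M", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("plate map ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  key <- paste(df$plate_id, df$row, df$col)
  if (anyDuplicated(key)) {
    lines <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate well definition at data row(s) ",
         paste(lines, collapse = ", "), " of ", path)
  }
  plate_layout(df$plate_id, df$row, df$col, df$role, df$compound_id,
               df$concentration_M, df$replicate)
}

#' Write a plate map to CSV
#'
#' @param layout an [plate_layout()] object.
#' @param path output CSV path.
#' @param metadata optional named character vector written as `# key=value`
#'   header comments (e.g. seed and config hash).
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(layout, path, metadata = NULL) {
  cols <- c("plate_id", "row", "col", "role", "compound_id",
            "concentration_M", "replicate")
  write_csv_with_header(as.data.frame(layout)[cols], path, metadata)
}

write_csv_with_header <- function(df, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(metadata))
    writeLines(sprintf("# %s=%s", names(metadata), unname(metadata)), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
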