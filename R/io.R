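# Extended-XYZ trajectory I/O and run-configuration round-tripping.
#
# Dialect: the comment line carries Lattice="Lx 0 0 0 Ly 0 0 0 Lz",
# sigma=<value> and phi=<value>; per-atom columns are the element tag HS,
# x, y, z, chain_id (0-based) and index_in_chain (0-based).  A trajectory
# is a concatenation of frames.

#' Write chain systems to an extended-XYZ file
#'
#' @param frames A `chain_system` or list of them.
#' @param path Output file.
#' @param digits Coordinate precision (default 17: round-trip exact).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, digits = 17) {
  if (inherits(frames, "chain_system")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (sys in frames) {
    chain_id <- integer(n_atoms(sys))
    idx_in <- integer(n_atoms(sys))
    for (c in seq_along(sys$chains)) {
      ch <- sys$chains[[c]]
      chain_id[ch] <- c - 1L
      idx_in[ch] <- seq_along(ch) - 1L
    }
    L <- sys$box$L
    writeLines(sprintf("%d", n_atoms(sys)), con)
    writeLines(sprintf(
      paste0('Lattice="%.*g 0 0 0 %.*g 0 0 0 %.*g" ',
             'Properties=species:S:1:pos:R:3:chain_id:I:1:index_in_chain:I:1 ',
             "sigma=%g phi=%.8f"),
      digits, L[1], digits, L[2], digits, L[3], sys$sigma,
      packing_fraction(sys)), con)
    writeLines(sprintf("HS %.*g %.*g %.*g %d %d",
                       digits, sys$pos[, 1], digits, sys$pos[, 2],
                       digits, sys$pos[, 3], chain_id, idx_in), con)
  }
  invisible(path)
}

#' Read chain systems from an extended-XYZ file
#'
#' Coordinates recorded at a sigma other than 1 are rescaled to internal
#' units on read.  Each frame is validated; with `permissive = TRUE`
#' invalid frames are returned with the violation report attached as
#' attribute `violations` instead of raising an error.
#'
#' @param path Input file.
#' @param permissive Keep invalid frames (default FALSE).
#' @return List of `chain_system` frames.
#' @export
read_xyz <- function(path, permissive = FALSE) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  frame_no <- 0
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) {
      stop("malformed header at line ", i, ": expected an atom count")
    }
    n <- as.integer(lines[i])
    frame_no <- frame_no + 1
    comment <- lines[i + 1]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]][2]
    if (is.na(lat)) stop("frame ", frame_no, ": missing Lattice record")
    lv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
    if (length(lv) != 9 || any(lv[-c(1, 5, 9)] != 0)) {
      stop("frame ", frame_no, ": box must be orthorhombic (diagonal lattice)")
    }
    sigma <- parse_kv(comment, "sigma", default = 1)
    atoms <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(atoms), "\\s+")
    bad <- which(lengths(parts) < 6)
    if (length(bad)) {
      stop("frame ", frame_no, ": missing chain_id/index_in_chain at line ",
           i + 1 + bad[1])
    }
    m <- matrix(unlist(parts), ncol = length(parts[[1]]), byrow = TRUE)
    pos <- matrix(as.numeric(m[, 2:4]), ncol = 3)
    chain_id <- as.integer(m[, 5])
    idx_in <- as.integer(m[, 6])
    chains <- lapply(sort(unique(chain_id)), function(ci) {
      sel <- which(chain_id == ci)
      if (anyDuplicated(idx_in[sel])) {
        stop("frame ", frame_no, ": duplicate index_in_chain within chain ",
             ci, " (first at line ",
             i + 1 + sel[duplicated(idx_in[sel])][1], ")")
      }
      sel[order(idx_in[sel])]
    })
    sys <- try(chain_system(pos, chains, simulation_box(lv[c(1, 5, 9)]),
                            sigma = sigma), silent = TRUE)
    if (inherits(sys, "try-error")) {
      stop("frame ", frame_no, ": ", attr(sys, "condition")$message)
    }
    v <- validate_system(sys)
    if (!v$valid) {
      if (!permissive) {
        stop("frame ", frame_no, " violates hard-sphere constraints (",
             nrow(v$overlaps), " overlaps, ", nrow(v$bad_bonds), " bad bonds)")
      }
      attr(sys, "violations") <- v
    }
    frames[[frame_no]] <- sys
    i <- i + 2 + n
  }
  frames
}

parse_kv <- function(comment, key, default = NULL) {
  m <- regmatches(comment, regexec(paste0(key, "=([-0-9.eE+]+)"), comment))[[1]]
  if (length(m) < 2) return(default)
  as.numeric(m[2])
}

#' Read or write a declarative run configuration
#'
#' One YAML document holding the generation, compression, simulation and
#' analysis settings plus the seed; round-trips losslessly and rejects
#' unknown keys.
#'
#' @param path File path.
#' @param config Named list of settings.
#' @return `read_run_config()` the configuration list; `write_run_config()`
#'   the path, invisibly.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required for run configurations")
  }
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "ensemble", "movemix", "generate", "compress",
             "simulate", "analyze", "output")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required for run configurations")
  }
  yaml::write_yaml(config, path)
  invisible(path)
}
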