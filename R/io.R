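#' @importFrom rlang .data
NULL

# 32-bit FNV-1a hash of a character string, as 8 hex digits. Used to stamp
# output files with a fingerprint of the resolved configuration.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor into the low 16 bits (the byte cannot touch the high half), then
    # multiply by the FNV prime 16777619 modulo 2^32 in 16-bit halves --
    # all arithmetic stays well inside double precision
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                              digits = NA))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

output_header <- function(seed = NA, config = NULL) {
  c(sprintf("# labreed %s",
            as.character(utils::packageVersion("labreed"))),
    sprintf("# seed: %s", ifelse(is.na(seed), "NA", seed)),
    sprintf("# config_hash: %s",
            if (is.null(config)) "none" else config_hash(config)))
}

hap_row_names <- function(N) {
  paste0("i", rep(seq_len(N), each = 2L), "_h", rep(1:2, N))
}

#' Write / read a haplotype panel as TSV tracks
#'
#' Serialises a panel as one TSV per track (genotype `G`, ancestry `A`,
#' founder labels `F`), written to `<prefix>_G.tsv` etc. Rows are
#' haplotypes, labelled `i<index>_h<1|2>` with the two copies of an
#' individual interleaved; the header row holds the SNP genetic positions
#' in Morgans. A few leading `#` comment lines record the package version,
#' seed and configuration hash. Round trips are bit-exact.
#'
#' @param panel A [hap_panel()].
#' @param prefix Output path prefix.
#' @param genome_map A [genome_map()] supplying the position header.
#' @param seed,config Optional provenance recorded in the header comments.
#' @return `write_panel()` returns the three file paths invisibly;
#'   `read_panel()` returns a list with `panel` and `map`.
#' @export
write_panel <- function(panel, prefix, genome_map, seed = NA, config = NULL) {
  stopifnot(is_hap_panel(panel), is_genome_map(genome_map),
            genome_map$L == n_loci(panel))
  paths <- paste0(prefix, "_", c("G", "A", "F"), ".tsv")
  names(paths) <- c("G", "A", "F")
  hdr <- output_header(seed, config)
  for (track in c("G", "A", "F")) {
    m <- track_to_rows(panel[[track]])
    con <- file(paths[[track]], "w")
    writeLines(hdr, con)
    writeLines(paste(c("haplotype", format(genome_map$positions, digits = 15,
                                           trim = TRUE, scientific = FALSE)),
                     collapse = "\t"), con)
    utils::write.table(
      data.frame(haplotype = hap_row_names(n_individuals(panel)), m,
                 check.names = FALSE),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    close(con)
  }
  invisible(paths)
}

# N x 2 x L array -> 2N x L matrix with copies interleaved (i1_h1, i1_h2, ...)
track_to_rows <- function(track) {
  N <- dim(track)[1]; L <- dim(track)[3]
  m <- matrix(0L, 2L * N, L)
  m[seq(1L, 2L * N, by = 2L), ] <- matrix(track[, 1L, ], N, L)
  m[seq(2L, 2L * N, by = 2L), ] <- matrix(track[, 2L, ], N, L)
  m
}

rows_to_track <- function(m) {
  N <- nrow(m) %/% 2L
  L <- ncol(m)
  arr <- array(0L, c(N, 2L, L))
  arr[, 1L, ] <- m[seq(1L, 2L * N, by = 2L), ]
  arr[, 2L, ] <- m[seq(2L, 2L * N, by = 2L), ]
  arr
}

#' @rdname write_panel
#' @param t Generation index assigned to the read panel (default 0).
#' @export
read_panel <- function(prefix, t = 0L) {
  paths <- paste0(prefix, "_", c("G", "A", "F"), ".tsv")
  tracks <- lapply(paths, read_hap_matrix_file)
  pos <- tracks[[1]]$positions
  panel <- hap_panel(rows_to_track(tracks[[1]]$m),
                     rows_to_track(tracks[[2]]$m),
                     rows_to_track(tracks[[3]]$m), t = t)
  list(panel = panel, map = genome_map(length(pos), D = pos[length(pos)],
                                       positions = pos))
}

# Read one haplotype-matrix TSV: '#' comments, header of positions, rows
# "sample_h1"/"sample_h2". Returns list(m, positions, ids).
read_hap_matrix_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  positions <- as.numeric(hdr[-1L])
  if (anyNA(positions)) {
    stop("non-numeric position header in ", path, call. = FALSE)
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    stop("positions not strictly increasing in ", path, call. = FALSE)
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- vapply(body, `[[`, character(1), 1L)
  m <- do.call(rbind, lapply(seq_along(body), function(r) {
    v <- suppressWarnings(as.integer(body[[r]][-1L]))
    if (length(v) != length(positions)) {
      stop("row ", r, " (", ids[r], ") in ", path, " has ", length(v),
           " values, expected ", length(positions), call. = FALSE)
    }
    if (anyNA(v)) {
      stop("non-integer value at row ", r, " (", ids[r], "), column ",
           which(is.na(v))[1L], " in ", path, call. = FALSE)
    }
    v
  }))
  if (nrow(m) %% 2L != 0L) {
    stop("odd number of haplotype rows in ", path, call. = FALSE)
  }
  list(m = m, positions = positions, ids = ids)
}

#' Read phased haplotype and ancestry matrices
#'
#' Real-data entry point: reads a genotype matrix and a matching
#' local-ancestry matrix (same TSV layout as [write_panel()]: haplotype rows
#' `sample_h1` / `sample_h2` interleaved, binary values, header of SNP
#' positions in Morgans) and assembles a [hap_panel()]. Founder labels are
#' initialised fresh — every input haplotype is treated as a founder
#' haplotype — so kinship measures are defined relative to the input
#' generation.
#'
#' @param path_genotypes,path_ancestry Paths to the two TSVs (identical
#'   shape).
#' @return A list with `panel` and `map`.
#' @export
read_haplotype_ancestry_matrices <- function(path_genotypes, path_ancestry) {
  g <- read_hap_matrix_file(path_genotypes)
  a <- read_hap_matrix_file(path_ancestry)
  if (!identical(dim(g$m), dim(a$m))) {
    stop("genotype matrix is ", nrow(g$m), " x ", ncol(g$m),
         " but ancestry matrix is ", nrow(a$m), " x ", ncol(a$m),
         call. = FALSE)
  }
  for (nm in list(list("genotype", g), list("ancestry", a))) {
    bad <- which(nm[[2]]$m != 0L & nm[[2]]$m != 1L, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop("non-binary ", nm[[1]], " value at row ", bad[1, 1], " (",
           nm[[2]]$ids[bad[1, 1]], "), column ", bad[1, 2], call. = FALSE)
    }
  }
  N <- nrow(g$m) %/% 2L
  panel <- hap_panel(rows_to_track(g$m), rows_to_track(a$m),
                     init_founder_labels(N, ncol(g$m)), t = 0L)
  pos <- g$positions
  list(panel = panel,
       map = genome_map(length(pos), D = pos[length(pos)], positions = pos))
}

#' Read a phased biallelic VCF plus ancestry sidecar
#'
#' Optional convenience reader: takes a VCF whose genotypes are all phased
#' (`0|1` style) and biallelic, plus an ancestry matrix in the TSV layout of
#' [read_haplotype_ancestry_matrices()], and returns the same panel the
#' matrix reader would give on equivalent input. Sites are mapped to genetic
#' positions via `morgans_per_bp`. Requires the `vcfR` package.
#'
#' @param path_vcf Path to the VCF (uncompressed or gzipped).
#' @param path_ancestry Path to the ancestry TSV.
#' @param morgans_per_bp Conversion from physical position to genetic map
#'   position (default `1e-8`, i.e. 1 cM/Mb).
#' @return A list with `panel` and `map`.
#' @export
read_phased_vcf <- function(path_vcf, path_ancestry, morgans_per_bp = 1e-8) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_phased_vcf() requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path_vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-site VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop("multiallelic site at ", fix[which(multi)[1], "CHROM"], ":",
         fix[which(multi)[1], "POS"], call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  site_id <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  miss <- matrix(is.na(gt) | gt %in% c(".", "./.", ".|."),
                 nrow(gt), ncol(gt))
  bad <- which(miss, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("missing genotype at ", site_id[bad[1, 1]], " sample ",
         colnames(gt)[bad[1, 2]], call. = FALSE)
  }
  unph <- which(matrix(!grepl("^[01]\\|[01]$", gt), nrow(gt), ncol(gt)),
                arr.ind = TRUE)
  if (nrow(unph) > 0L) {
    stop("unphased or non-binary genotype '", gt[unph[1, 1], unph[1, 2]],
         "' at ", site_id[unph[1, 1]], " sample ",
         colnames(gt)[unph[1, 2]], call. = FALSE)
  }
  L <- nrow(gt); N <- ncol(gt)
  h1 <- matrix(as.integer(substr(gt, 1, 1)), L, N)
  h2 <- matrix(as.integer(substr(gt, 3, 3)), L, N)
  # interleave to the matrix-reader row layout: sample_h1, sample_h2, ...
  m <- matrix(0L, 2L * N, L)
  m[seq(1L, 2L * N, by = 2L), ] <- t(h1)
  m[seq(2L, 2L * N, by = 2L), ] <- t(h2)
  a <- read_hap_matrix_file(path_ancestry)
  if (!identical(dim(a$m), dim(m))) {
    stop("ancestry matrix is ", nrow(a$m), " x ", ncol(a$m),
         " but VCF implies ", 2L * N, " x ", L, call. = FALSE)
  }
  panel <- hap_panel(rows_to_track(m), rows_to_track(a$m),
                     init_founder_labels(N, L), t = 0L)
  pos <- as.numeric(fix[, "POS"]) * morgans_per_bp
  if (any(diff(pos) <= 0)) stop("VCF positions not strictly increasing",
                                call. = FALSE)
  list(panel = panel,
       map = genome_map(L, D = pos[L], positions = pos))
}

#' Write / read a score trajectory TSV
#'
#' One row per (replicate, generation) with the five population scores;
#' leading `#` comments record the package version, seed and config hash.
#'
#' @param trajectory A tibble from [run_program()] or [run_replicates()].
#' @param path Output path.
#' @param seed,config Optional provenance for the header.
#' @return The path, invisibly; `read_trajectory()` returns the tibble.
#' @export
write_trajectory <- function(trajectory, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  writeLines(output_header(seed, config), con)
  utils::write.table(as.data.frame(trajectory), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      comment.char = "#"))
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a nested configuration file with optional blocks `map`
#' (`L`, `D`), `history`, `breeding` and `seed`, each mirroring the
#' corresponding constructor's argument names, and returns a
#' [program_config()] with unspecified values at their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [program_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  L <- raw$map$L %||% 500
  D <- raw$map$D %||% 5
  N <- raw$history$N %||% raw$breeding$capacity %||% 150
  hist_args <- raw$history %||% list()
  hist_args$L <- L
  hist_args$N <- N
  history <- do.call(wild_history_config, hist_args)
  breed_args <- raw$breeding %||% list()
  breed_args$capacity <- breed_args$capacity %||% N
  breeding <- do.call(breeding_config, breed_args)
  program_config(L = L, D = D, history = history, breeding = breeding,
                 N = N, seed = raw$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
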