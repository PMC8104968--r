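# Readers and writers for the plain-text formats the pipeline exchanges:
# minimal VCFv4.2 genotypes, OFF / ASCII-PLY triangle meshes, PGM binary
# section rasters, TSV kinship matrices and BED interval files.

#' Write genotype dosages as a minimal VCFv4.2 file
#'
#' Emits CHROM, POS, ID, REF, ALT and per-individual GT calls. Dosage 0 is
#' written as 0/0, 1 as 0/1, 2 as 1/1; missing as ./.
#'
#' @param g genotype object as returned by [simulate_pedigree_genotypes()]:
#'   list with `dosage` (SNPs x individuals), `chrom`, `pos`.
#' @param path output file.
#' @export
write_vcf <- function(g, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(g$dosage)), collapse = "\t")),
             con)
  gt <- matrix(gt_code[as.character(g$dosage)], nrow = nrow(g$dosage))
  gt[is.na(gt)] <- "./."
  lines <- paste(g$chrom, g$pos, rownames(g$dosage) %||%
                   paste0("snp", seq_len(nrow(gt))),
                 "A", "G", ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read genotype dosages from a VCF file
#'
#' Parses GT fields into allele dosages in \{0, 1, 2, NA\}. Multiallelic
#' records are kept (flagged) so that [filter_snps()] can drop them.
#'
#' @param path VCF file (plain text).
#' @return genotype list with `dosage`, `chrom`, `pos`, `biallelic`.
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- vcfR::getALT(v)
  count_alt <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (length(al) == 0 || anyNA(al) || any(al == "." | al == ""))
        return(NA_real_)
      sum(al != "0")
    }, numeric(1))
  }
  dosage <- t(apply(gt, 1, count_alt))
  dimnames(dosage) <- dimnames(gt)
  list(dosage = dosage,
       chrom = as.character(vcfR::getCHROM(v)),
       pos = as.integer(vcfR::getPOS(v)),
       biallelic = !grepl(",", alt))
}

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix, one 3-D vertex per row.
#' @param faces integer matrix, one triangle (three 1-based vertex indices)
#'   per row.
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- unname(as.matrix(vertices))
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop_arg("vertices must be n x 3")
  if (any(faces < 1L | faces > nrow(vertices)))
    stop_arg("face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
    stop_arg("degenerate faces (repeated vertex index)")
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' Unique undirected edges of a mesh
#' @param mesh a `triangle_mesh`.
#' @return integer matrix of vertex index pairs (sorted within row, unique).
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Euler characteristic (V - E + F) of a mesh
#' @param mesh a `triangle_mesh`.
#' @export
mesh_euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Write a mesh in OFF format
#' @param mesh a `triangle_mesh`.
#' @param path output file.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$faces), 0), con)
  writeLines(apply(format(mesh$vertices, trim = TRUE, digits = 17), 1,
                   paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read a triangle mesh from OFF or ASCII PLY
#' @param path mesh file; format chosen by extension (.off/.ply) or header.
#' @return a `triangle_mesh`.
#' @export
read_mesh <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^OFF", first)) read_off(path) else read_ply_ascii(path)
}

read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!grepl("^OFF", lines[1])) stop_arg("not an OFF file: ", path)
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    if (x[1] != 3L) stop_arg("non-triangular face in ", path)
    x[2:4] + 1L
  }))
  triangle_mesh(vtx, fc)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !any(grepl("format ascii", lines)))
    stop_arg("only ASCII PLY is supported: ", path)
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1",
                       grep("element vertex", lines[1:hdr_end], value = TRUE)))
  nf <- as.integer(sub(".*element face (\\d+).*", "\\1",
                       grep("element face", lines[1:hdr_end], value = TRUE)))
  body <- lines[(hdr_end + 1):length(lines)]
  vtx <- do.call(rbind, lapply(body[1:nv], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(body[(nv + 1):(nv + nf)], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    if (x[1] != 3L) stop_arg("non-triangular face in ", path)
    x[2:4] + 1L
  }))
  triangle_mesh(vtx, fc)
}

#' Write a binary section image as ASCII PGM (P2)
#' @param img 0/1 integer matrix (rows = image rows).
#' @param path output file.
#' @param pixel_mm pixel edge length in mm, stored in a comment line.
#' @export
write_pgm <- function(img, path, pixel_mm = NA_real_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("P2", con)
  if (!is.na(pixel_mm)) writeLines(paste0("# pixel_mm=", pixel_mm), con)
  writeLines(paste(ncol(img), nrow(img)), con)
  writeLines("1", con)
  writeLines(apply(img, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PGM (P2) section image
#' @param path PGM file.
#' @return list with `img` (0/1 matrix) and `pixel_mm` (NA if absent).
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "P2") stop_arg("only ASCII PGM (P2) is supported")
  pixel_mm <- NA_real_
  cm <- grep("^#", lines, value = TRUE)
  hit <- grep("pixel_mm=", cm, value = TRUE)
  if (length(hit)) pixel_mm <- as.numeric(sub(".*pixel_mm=", "", hit[1]))
  body <- lines[-1]
  body <- body[!grepl("^#", body)]
  vals <- as.integer(unlist(strsplit(trimws(paste(body, collapse = " ")),
                                     "\\s+")))
  w <- vals[1]; h <- vals[2]; maxv <- vals[3]
  img <- matrix(vals[-(1:3)], nrow = h, ncol = w, byrow = TRUE)
  list(img = (img > 0) + 0L, pixel_mm = pixel_mm)
}

#' Write a kinship matrix as TSV with ID header row and column
#' @param K kinship matrix with dimnames.
#' @param path output file.
#' @export
write_kinship_tsv <- function(K, path) {
  write_matrix_tsv(K, path, id_col = "id")
}

#' Read a kinship matrix written by [write_kinship_tsv()]
#' @param path TSV file.
#' @export
read_kinship_tsv <- function(path) {
  K <- read_matrix_tsv(path)
  colnames(K) <- rownames(K)
  K
}

#' Read genomic intervals from a BED file
#'
#' Intervals are returned 0-based half-open, the package's internal
#' convention (and BED's native one).
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  df
}

# Convert a 0-based half-open interval frame to GRanges (1-based closed).
intervals_to_granges <- function(df) {
  if (any(df$start >= df$end)) stop_arg("intervals must satisfy start < end")
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}
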