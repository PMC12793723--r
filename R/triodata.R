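#' Construct a trio genotype set
#'
#' Container for aligned child/mother/father genotype matrices. Genotypes are
#' coded 0/1/2 as the count of the coded (ALT) allele; `NA` marks missing
#' calls. Rows are SNPs, columns are trios.
#'
#' @param G,Zm,Zp I x J integer matrices of child, maternal and paternal
#'   coded-allele counts.
#' @param snp_meta data.frame with one row per SNP: columns `snp`, `chrom`,
#'   `pos`, `ref`, `alt`. Generated if `NULL`.
#' @param trio_ids data.frame with one row per trio: columns `child`,
#'   `mother`, `father`. Generated if `NULL`.
#' @return an object of class `trio_genotypes`.
#' @export
trio_genotypes <- function(G, Zm, Zp, snp_meta = NULL, trio_ids = NULL) {
  G <- as.matrix(G); Zm <- as.matrix(Zm); Zp <- as.matrix(Zp)
  if (!identical(dim(G), dim(Zm)) || !identical(dim(G), dim(Zp)))
    stop("G, Zm, Zp must share the same I x J dimensions")
  for (m in list(G, Zm, Zp)) {
    v <- m[!is.na(m)]
    if (length(v) && !all(v %in% 0:2))
      stop("genotype codes must be 0, 1, 2 or NA")
  }
  storage.mode(G) <- "integer"; storage.mode(Zm) <- "integer"
  storage.mode(Zp) <- "integer"
  dimnames(G) <- dimnames(Zm) <- dimnames(Zp) <- NULL
  I <- nrow(G); J <- ncol(G)
  if (is.null(snp_meta))
    snp_meta <- data.frame(snp = sprintf("snp%d", seq_len(I)),
                           chrom = "1", pos = seq_len(I),
                           ref = "A", alt = "G", stringsAsFactors = FALSE)
  if (is.null(trio_ids))
    trio_ids <- data.frame(child = sprintf("child%d", seq_len(J)),
                           mother = sprintf("mother%d", seq_len(J)),
                           father = sprintf("father%d", seq_len(J)),
                           stringsAsFactors = FALSE)
  stopifnot(nrow(snp_meta) == I, nrow(trio_ids) == J)
  if (anyDuplicated(trio_ids$child)) stop("duplicated child identifier")
  parents <- c(trio_ids$mother, trio_ids$father)
  if (anyDuplicated(parents)) stop("an individual appears as parent in more than one trio")
  if (any(parents %in% trio_ids$child))
    stop("an individual appears both as parent and child")
  structure(list(G = G, Zm = Zm, Zp = Zp, snp_meta = snp_meta,
                 trio_ids = trio_ids),
            class = "trio_genotypes")
}

#' @export
print.trio_genotypes <- function(x, ...) {
  cat(sprintf("trio_genotypes: %d SNPs x %d trios\n", nrow(x$G), ncol(x$G)))
  invisible(x)
}

#' @export
dim.trio_genotypes <- function(x) dim(x$G)

#' Load trio genotypes from a VCF and a PLINK .fam pedigree
#'
#' Reads unphased (or phased; phase is ignored) biallelic SNP genotypes for
#' all complete trios defined by the pedigree. Multi-allelic and non-SNP
#' records are skipped with a logged count. Trios whose members are missing
#' from the VCF are dropped with a warning.
#'
#' @param vcf_path path to an uncompressed or gzipped VCF (v4.x) with GT.
#' @param fam_path path to a PLINK .fam file
#'   (FID IID PAT MAT SEX PHENO, whitespace-separated, no header).
#' @return a [trio_genotypes] object.
#' @export
load_trios <- function(vcf_path, fam_path) {
  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           colClasses = "character")
  kids <- fam[fam$pat != "0" & fam$mat != "0", , drop = FALSE]
  if (anyDuplicated(kids$iid)) stop("duplicated child in .fam")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  have <- kids$pat %in% samples & kids$mat %in% samples & kids$iid %in% samples
  if (any(!have)) {
    warning(sprintf("%d trio(s) dropped: member(s) absent from VCF", sum(!have)))
    kids <- kids[have, , drop = FALSE]
  }
  if (nrow(kids) == 0L) stop("no complete trios found")

  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0)
    message(sprintf("load_trios: %d multi-allelic/non-SNP record(s) skipped", n_skip))
  if (!any(is_snp)) stop("no biallelic SNP records in VCF")
  gt <- vcfR::extract.gt(v[is_snp, ], element = "GT")
  fix <- fix[is_snp, , drop = FALSE]

  code <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    out <- vapply(a, function(al) {
      al <- suppressWarnings(as.integer(al))
      if (length(al) != 2L || anyNA(al)) return(NA_integer_)
      sum(al != 0L)
    }, integer(1))
    out
  }
  gmat <- function(ids) {
    m <- gt[, ids, drop = FALSE]
    matrix(code(m), nrow = nrow(gt), ncol = length(ids))
  }
  snp_meta <- data.frame(snp = ifelse(is.na(fix$ID) | fix$ID == ".",
                                      paste0(fix$CHROM, ":", fix$POS), fix$ID),
                         chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  trio_genotypes(G = gmat(kids$iid), Zm = gmat(kids$mat), Zp = gmat(kids$pat),
                 snp_meta = snp_meta,
                 trio_ids = data.frame(child = kids$iid, mother = kids$mat,
                                       father = kids$pat, stringsAsFactors = FALSE))
}

#' Read / write trio genotypes as a plain TSV matrix
#'
#' SNP-major fixture dialect: metadata columns `snp`, `chrom`, `pos`, `ref`,
#' `alt`, then for each trio three integer columns
#' `<child>.child`, `<child>.mother`, `<child>.father` holding 0/1/2 codes
#' ("NA" for missing).
#'
#' @param path TSV path.
#' @param x a [trio_genotypes] object.
#' @return `read_trio_matrix` returns a [trio_genotypes]; `write_trio_matrix`
#'   returns `path` invisibly.
#' @export
read_trio_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("snp", "chrom", "pos", "ref", "alt")
  gcols <- setdiff(names(d), meta_cols)
  role <- sub("^.*\\.", "", gcols)
  child_of <- sub("\\.[^.]*$", "", gcols)
  kids <- unique(child_of)
  pick <- function(r) as.matrix(d[, gcols[role == r], drop = FALSE])
  # parent identifiers are not stored in the matrix dialect; regenerate them
  trio_genotypes(G = pick("child"), Zm = pick("mother"), Zp = pick("father"),
                 snp_meta = d[, meta_cols],
                 trio_ids = data.frame(child = kids,
                                       mother = paste0(kids, ".m"),
                                       father = paste0(kids, ".f"),
                                       stringsAsFactors = FALSE))
}

#' @rdname read_trio_matrix
#' @export
write_trio_matrix <- function(x, path) {
  stopifnot(inherits(x, "trio_genotypes"))
  J <- ncol(x$G)
  cols <- list()
  for (j in seq_len(J)) {
    cid <- x$trio_ids$child[j]
    cols[[paste0(cid, ".child")]] <- x$G[, j]
    cols[[paste0(cid, ".mother")]] <- x$Zm[, j]
    cols[[paste0(cid, ".father")]] <- x$Zp[, j]
  }
  d <- cbind(x$snp_meta, as.data.frame(cols, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a child phenotype vector aligned to trio order
#'
#' @param path TSV with header columns `id` and `value`.
#' @param trio_ids data.frame with a `child` column (from [trio_genotypes]),
#'   or a character vector of child identifiers.
#' @param kind `"auto"` (binary iff all non-missing values are 0/1),
#'   `"quantitative"`, or `"binary"`.
#' @return list with `values` (numeric, `NA` where missing), `kind`, and
#'   logical `missing`.
#' @export
load_phenotypes <- function(path, trio_ids, kind = c("auto", "quantitative", "binary")) {
  kind <- match.arg(kind)
  ids <- if (is.data.frame(trio_ids)) trio_ids$child else as.character(trio_ids)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "value") %in% names(d)))
    stop("phenotype file must have columns 'id' and 'value'")
  bad <- !is.na(d$value) & is.na(suppressWarnings(as.numeric(d$value)))
  if (any(bad))
    stop(sprintf("non-numeric phenotype value in row %d (id %s)",
                 which(bad)[1], d$id[which(bad)[1]]))
  vals <- as.numeric(d$value)[match(ids, d$id)]
  if (anyNA(vals))
    warning(sprintf("%d child(ren) missing from phenotype file", sum(is.na(vals))))
  if (kind == "auto")
    kind <- if (all(vals[!is.na(vals)] %in% c(0, 1))) "binary" else "quantitative"
  if (kind == "binary" && !all(vals[!is.na(vals)] %in% c(0, 1)))
    stop("binary phenotype contains values other than 0/1")
  list(values = vals, kind = kind, missing = is.na(vals))
}

#' Write a per-SNP result table as TSV
#'
#' One row per SNP; columns depend on the result class (TMT or TDT) and
#' include identifier, position, coded allele, sample sizes, estimate,
#' statistic, p-value and a status flag.
#'
#' @param results data.frame from [tmt_test()] or [tdt_test()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results must be a nonempty data.frame")
  ok <- tryCatch({
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results: ", conditionMessage(e)))
  invisible(path)
}

#' Write a trio cohort as plain-text VCF + .fam (+ optional phenotype TSV)
#'
#' Emits a minimal GT-only VCF v4.2 with 3J samples (children then mothers
#' then fathers), a matching PLINK .fam defining the trios, and, when `y` is
#' given, a phenotype TSV. Output is uncompressed text and round-trips
#' through [load_trios()].
#'
#' @param x a [trio_genotypes] object.
#' @param prefix output path prefix; writes `<prefix>.vcf`, `<prefix>.fam`
#'   and (optionally) `<prefix>.pheno.tsv`.
#' @param y optional numeric phenotype vector of length J.
#' @return named character vector of written paths, invisibly.
#' @export
write_trio_vcf <- function(x, prefix, y = NULL) {
  stopifnot(inherits(x, "trio_genotypes"))
  I <- nrow(x$G); J <- ncol(x$G)
  gt_str <- function(g) ifelse(is.na(g), "./.",
                               c("0/0", "0/1", "1/1")[g + 1L])
  samples <- c(x$trio_ids$child, x$trio_ids$mother, x$trio_ids$father)
  body <- matrix("", I, 3L * J)
  body[, seq_len(J)] <- gt_str(x$G)
  body[, J + seq_len(J)] <- gt_str(x$Zm)
  body[, 2L * J + seq_len(J)] <- gt_str(x$Zp)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- paste(x$snp_meta$chrom, x$snp_meta$pos, x$snp_meta$snp,
                x$snp_meta$ref, x$snp_meta$alt, ".", "PASS", ".", "GT",
                apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  vcf_path <- paste0(prefix, ".vcf")
  writeLines(c(header, rows), vcf_path)
  fam <- rbind(
    data.frame(fid = x$trio_ids$child, iid = x$trio_ids$child,
               pat = x$trio_ids$father, mat = x$trio_ids$mother,
               sex = 0L, pheno = -9L, stringsAsFactors = FALSE),
    data.frame(fid = x$trio_ids$child, iid = x$trio_ids$mother,
               pat = "0", mat = "0", sex = 2L, pheno = -9L,
               stringsAsFactors = FALSE),
    data.frame(fid = x$trio_ids$child, iid = x$trio_ids$father,
               pat = "0", mat = "0", sex = 1L, pheno = -9L,
               stringsAsFactors = FALSE))
  fam_path <- paste0(prefix, ".fam")
  utils::write.table(fam, fam_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths <- c(vcf = vcf_path, fam = fam_path)
  if (!is.null(y)) {
    stopifnot(length(y) == J)
    ph_path <- paste0(prefix, ".pheno.tsv")
    utils::write.table(data.frame(id = x$trio_ids$child, value = y),
                       ph_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pheno = ph_path)
  }
  invisible(paths)
}
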