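# Minimal XLSX emitter: worksheet XML with inline strings packed into a zip
# container built directly (deflate streams via memCompress, CRC-32 below).
# Only what the workbook round-trip needs; reading goes through readxl.

.crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  for (i in 0:255) {
    crc <- i
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 1L) != 0L) {
        bitwXor(bitwShiftR(crc, 1L), poly)
      } else {
        bitwShiftR(crc, 1L)
      }
    }
    tab[i + 1L] <- crc
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8L), .crc32_table[idx + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else as.double(crc)
}

int_le <- function(x, n) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# raw deflate stream: memCompress "gzip" yields zlib framing (2-byte header,
# 4-byte Adler-32 trailer) which is stripped here
deflate_raw <- function(bytes) {
  z <- memCompress(bytes, type = "gzip")
  z[3:(length(z) - 4L)]
}

zip_write <- function(files, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  offsets <- integer(length(files))
  sizes <- vector("list", length(files))
  offset <- 0
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    data <- files[[i]]
    comp <- deflate_raw(data)
    crc <- crc32(data)
    header <- c(
      int_le(0x04034b50, 4), int_le(20, 2), int_le(0, 2), int_le(8, 2),
      int_le(0, 2), int_le(0x21, 2),            # time 0, date 1980-01-01
      int_le(crc, 4), int_le(length(comp), 4), int_le(length(data), 4),
      int_le(length(name), 2), int_le(0, 2)
    )
    offsets[i] <- offset
    sizes[[i]] <- list(crc = crc, comp = length(comp), uncomp = length(data))
    writeBin(c(header, name, comp), con)
    offset <- offset + length(header) + length(name) + length(comp)
  }
  cd_start <- offset
  cd_len <- 0
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    s <- sizes[[i]]
    entry <- c(
      int_le(0x02014b50, 4), int_le(20, 2), int_le(20, 2), int_le(0, 2),
      int_le(8, 2), int_le(0, 2), int_le(0x21, 2),
      int_le(s$crc, 4), int_le(s$comp, 4), int_le(s$uncomp, 4),
      int_le(length(name), 2), int_le(0, 2), int_le(0, 2), int_le(0, 2),
      int_le(0, 2), int_le(0, 4), int_le(offsets[i], 4)
    )
    writeBin(c(entry, name), con)
    cd_len <- cd_len + length(entry) + length(name)
  }
  eocd <- c(
    int_le(0x06054b50, 4), int_le(0, 2), int_le(0, 2),
    int_le(length(files), 2), int_le(length(files), 2),
    int_le(cd_len, 4), int_le(cd_start, 4), int_le(0, 2)
  )
  writeBin(eocd, con)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

col_letter <- function(j) {
  out <- ""
  while (j > 0) {
    out <- paste0(LETTERS[(j - 1L) %% 26L + 1L], out)
    j <- (j - 1L) %/% 26L
  }
  out
}

sheet_xml <- function(df) {
  cell <- function(i, j, value) {
    ref <- paste0(col_letter(j), i)
    if (is.na(value)) return("")
    if (is.numeric(value)) {
      sprintf('<c r="%s"><v>%s</v></c>', ref, sprintf("%.17g", value))
    } else {
      sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
              ref, xml_escape(as.character(value)))
    }
  }
  rows <- character(nrow(df) + 1L)
  rows[1L] <- paste0('<row r="1">',
    paste(vapply(seq_along(df), function(j) cell(1L, j, names(df)[j]), character(1)),
          collapse = ""), "</row>")
  for (i in seq_len(nrow(df))) {
    rows[i + 1L] <- paste0(sprintf('<row r="%d">', i + 1L),
      paste(vapply(seq_along(df), function(j) cell(i + 1L, j, df[[j]][i]), character(1)),
            collapse = ""), "</row>")
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>")
}

xlsx_write <- function(sheets, path) {
  ns_main <- "http://schemas.openxmlformats.org/spreadsheetml/2006/main"
  ns_rel <- "http://schemas.openxmlformats.org/officeDocument/2006/relationships"
  n <- length(sheets)
  content_types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(n)), collapse = ""),
    "</Types>")
  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    sprintf('<Relationship Id="rId1" Type="%s/officeDocument" Target="xl/workbook.xml"/>', ns_rel),
    "</Relationships>")
  workbook <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    sprintf('<workbook xmlns="%s" xmlns:r="%s"><sheets>', ns_main, ns_rel),
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(names(sheets)), seq_len(n), seq_len(n)), collapse = ""),
    "</sheets></workbook>")
  wb_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="%s/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(n), ns_rel, seq_len(n)), collapse = ""),
    sprintf('<Relationship Id="rId%d" Type="%s/styles" Target="styles.xml"/>', n + 1L, ns_rel),
    "</Relationships>")
  styles <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    sprintf('<styleSheet xmlns="%s">', ns_main),
    '<fonts count="1"><font/></fonts><fills count="1"><fill/></fills>',
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf/></cellStyleXfs>',
    '<cellXfs count="1"><xf numFmtId="0" xfId="0"/></cellXfs>',
    "</styleSheet>")
  files <- c(
    list("[Content_Types].xml" = charToRaw(content_types),
         "_rels/.rels" = charToRaw(rels),
         "xl/workbook.xml" = charToRaw(workbook),
         "xl/_rels/workbook.xml.rels" = charToRaw(wb_rels),
         "xl/styles.xml" = charToRaw(styles)),
    stats::setNames(
      purrr::map(sheets, ~ charToRaw(sheet_xml(.x))),
      sprintf("xl/worksheets/sheet%d.xml", seq_len(n)))
  )
  zip_write(files, path)
}
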