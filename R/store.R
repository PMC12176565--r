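#' Write / read a spectrogram store directory
#'
#' A store is a directory of 8-bit grayscale PNGs plus a `labels.csv`
#' (`file,parent_id,index,label`) — the on-disk interchange format between
#' the spectrogram stage and training. PNG quantization (1/255) applies.
#'
#' @param images list of `spectrogram_image`
#' @param dir store directory (created if missing)
#' @return the directory (write) / list of `spectrogram_image` (read),
#'   invisibly for the writer
#' @export
write_spectrogram_dir <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    fname <- sprintf("%s_%03d.png", im$parent_id, im$index)
    write_spectrogram_png(im, file.path(dir, fname))
    data.frame(file = fname, parent_id = im$parent_id, index = im$index,
               label = im$label)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "labels.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_spectrogram_dir
#' @export
read_spectrogram_dir <- function(dir) {
  meta <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    read_spectrogram_png(file.path(dir, meta$file[i]),
                         parent_id = meta$parent_id[i],
                         index = meta$index[i], label = meta$label[i])
  })
}
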