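# DICOM fixtures are written at test time with pydicom (independent writer),
# so the package's reader is checked against a third-party implementation.

write_dicom_fixture <- function(dir, z_positions = c(0, 5, 10),
                                rows = 8L, cols = 10L,
                                slope = 2, intercept = -1024) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  script <- sprintf('
import numpy as np, pydicom
from pydicom.dataset import FileDataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
zs = [%s]
rows, cols = %d, %d
for i, z in enumerate(zs):
    arr = ((np.arange(rows*cols, dtype=np.int16).reshape(rows, cols)) * (i + 1)) %% 2000
    ds = FileDataset("%s/s%%d.dcm" %% i, {}, file_meta=FileMetaDataset(),
                     preamble=b"\\0" * 128)
    ds.file_meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds.file_meta.MediaStorageSOPClassUID = generate_uid()
    ds.file_meta.MediaStorageSOPInstanceUID = generate_uid()
    ds.Rows, ds.Columns = rows, cols
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 1; ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.PixelSpacing = ["0.8", "0.7"]
    ds.SliceThickness = "5"
    ds.InstanceNumber = i + 1
    ds.ImagePositionPatient = ["0", "0", str(float(z))]
    ds.RescaleSlope = "%g"; ds.RescaleIntercept = "%g"
    ds.PixelData = arr.tobytes()
    ds.save_as("%s/s%%d.dcm" %% i, write_like_original=False)
', paste(z_positions, collapse = ", "), rows, cols, dir, slope, intercept, dir)
  status <- system2("python", args = "-", input = script,
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("pydicom fixture writer failed: ", paste(status, collapse = "\n"))
  # same pixel formula, computed independently in R
  expected <- array(0, c(length(z_positions), rows, cols))
  base <- matrix(seq_len(rows * cols) - 1L, rows, cols, byrow = TRUE)
  for (i in seq_along(z_positions))
    expected[i, , ] <- (base * i) %% 2000 * slope + intercept
  expected
}
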