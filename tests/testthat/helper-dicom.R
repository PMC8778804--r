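# Generate small DICOM series at test time with pydicom (an independent
# writer), so the package's reader is checked against third-party output.

python_available <- function() nzchar(Sys.which("python"))

# Writes n_slices CT slices into dir.  File names are deliberately shuffled
# relative to slice position.  Returns TRUE on success.
write_dicom_series <- function(dir, n_slices = 3, rows = 8, cols = 8,
                               pixel_spacing = c(0.98, 0.98),
                               slice_step = 1.25, intercept = -1024,
                               slope = 1, series = 1, value_base = 100) {
  script <- sprintf('
import pydicom, numpy as np, os
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
outdir = r"%s"
n, rows, cols = %d, %d, %d
series_uid = "1.2.826.0.1.3680043.8.498.1.%d"
names = ["slice_%%d.dcm" %% k for k in reversed(range(n))]  # shuffled names
for i in range(n):
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.2"
    meta.MediaStorageSOPInstanceUID = generate_uid()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds = Dataset()
    ds.file_meta = meta
    ds.SOPClassUID = meta.MediaStorageSOPClassUID
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.Modality = "CT"
    ds.SeriesInstanceUID = series_uid
    ds.Rows, ds.Columns = rows, cols
    ds.PixelSpacing = [%f, %f]
    ds.SliceThickness = %f
    ds.ImagePositionPatient = [0.0, 0.0, i * %f]
    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]
    ds.BitsAllocated = 16
    ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 0
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.RescaleIntercept = %f
    ds.RescaleSlope = %f
    arr = np.full((rows, cols), %d + i, dtype=np.uint16)
    arr[0, 0] = %d + i + 7
    ds.PixelData = arr.tobytes()
    ds.is_little_endian = True
    ds.is_implicit_VR = False
    ds.save_as(os.path.join(outdir, names[i]), enforce_file_format=True)
print("ok")
', dir, n_slices, rows, cols, series, pixel_spacing[1], pixel_spacing[2],
    slice_step, slice_step, intercept, slope, value_base, value_base)
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = TRUE))
  any(grepl("^ok$", out))
}
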