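"""N4 bias-field estimation for a single 2D slice.

Usage: python n4_correct.py image.nii.gz mask.nii.gz field.nii.gz

Reads a slice and a binary estimation mask, runs SimpleITK's
N4BiasFieldCorrectionImageFilter with its default parameters, and writes the
multiplicative field (input / corrected, 1 outside support) as NIfTI.
"""
import sys

import SimpleITK as sitk


def main(image_path, mask_path, field_path):
    img = sitk.ReadImage(image_path, sitk.sitkFloat32)
    msk = sitk.ReadImage(mask_path, sitk.sitkUInt8)
    corr = sitk.N4BiasFieldCorrection(img, msk)
    arr_in = sitk.GetArrayFromImage(img)
    arr_out = sitk.GetArrayFromImage(corr)
    field = arr_in / arr_out
    field[~(field > 0)] = 1.0
    field[arr_out <= 0] = 1.0
    out = sitk.GetImageFromArray(field)
    out.CopyInformation(img)
    sitk.WriteImage(out, field_path)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], sys.argv[3])
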