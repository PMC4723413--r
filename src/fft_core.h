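#ifndef SKULLWAVE_FFT_CORE_H
#define SKULLWAVE_FFT_CORE_H

#include <complex>
#include <vector>
#include <cstddef>

namespace skw {

typedef std::complex<double> cplx;

// In-place 3-D complex FFT on an n1 x n2 x n3 array stored column-major
// (n1 fastest).  sign = -1 forward, +1 inverse (inverse is scaled by 1/N).
void fft3(cplx* a, int n1, int n2, int n3, int sign);

// 1-D plan interface (exposed for the spectral interpolator).
void fft1_batch(cplx* a, int len, int nbatch, long elem_stride,
                long batch_stride, int sign);

// true if n factors into 2,3,5 only
bool smooth5(int n);
// smallest 5-smooth integer >= n
int next_smooth5(int n);

} // namespace skw

#endif
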