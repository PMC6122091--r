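 Excitation energies and oscillator strengths:

 Excited State   1:      Singlet-A      4.5000 eV   275.52 nm  f=0.0100  <S**2>=0.000
      11 ->  21        0.70000

 Excited State   2:      Singlet-A      5.2000 eV   238.43 nm  f=0.0100  <S**2>=0.000
      12 ->  22        0.70000

 Excited State   3:      Singlet-A      6.0000 eV   206.64 nm  f=0.0100  <S**2>=0.000
      13 ->  23        0.70000

                    1/2[<0|r|b>*<b|rxdel|0> + (<0|rxdel|b>*<b|r|0>)*]
                    Rotatory Strengths (R) in cgs (10**-40 erg-esu-cm/Gauss)
       state          XX          YY          ZZ     R(length)
           1        0.1000     -0.2000      0.3000      8.0000
           2        0.2000     -0.4000      0.6000    -15.0000
           3        0.3000     -0.6000      0.9000    -10.0000

 SavETr:  write IOETrn=   770 NScale= 10
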