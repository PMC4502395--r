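>seed01 synthetic bHLH-like domain
KRRERNRVAAANARERRKMKGDNDCFDELASVLPPSKEEKLSQAQILSKAIEYIGSLQ
>seed02 synthetic bHLH-like domain
KRRETSRIAAYNAHERRRMKGGTDAYDELASVLPLSDEEKLSKRQILSKADEYIQSLQ
>seed03 synthetic bHLH-like domain
KRRENNRAAAANARERLRMKGLNDLKDELASVLPLADEEKLSPAQILSKAIEYIQTLQ
>seed04 synthetic bHLH-like domain
KRRERNRIAAANARERRRMKGLNDAFDERASVLTLSAEEKVSMAQILIKAIEYIASFQ
>seed05 synthetic bHLH-like domain
KRRMRNEIAAANARQRRRMKTLPDAFDEYASLAPLSDEEKLSKDQIISKAIEYIQKLQ
>seed06 synthetic bHLH-like domain
KRREINRHYAANAREKRRMKGLNDAFDELASVLLLSLEEKKDKAQILSKSIEFIQSLQ
>seed07 synthetic bHLH-like domain
LRRARDRIAEANARGSRRMKFLNDAFDEEALVLYLSDEEKLMKAIILSKAIEYIQSIQ
>seed08 synthetic bHLH-like domain
KRRERNRSAAANLLERRRMKGLNKKFDEGASTLPLSDEEKLSKAQILHKAKEYIQSLQ
>seed09 synthetic bHLH-like domain
KRRERNRIAAVPVRERRRMKILNDAFDELAPVLASSDEEKLSKAQILSKAIEYIQKLQ
>seed10 synthetic bHLH-like domain
KRRERNQIAAANARERRRMKGLNDAFVELASILPLSDEEKLSKAQILNKAIEYIQSLQ
>seed11 synthetic bHLH-like domain
SRHHRNRIAAANARYLRRMIGLEDAFDELASVLPLSDEEKLSKAQIDSKADEYIQSLQ
>seed12 synthetic bHLH-like domain
KRRERNRAAAANQREARRYKGLNYGFDELASVKPLSKEEKLSKAAIKSKAGEYIVSLQ
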