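>SYNTOX01 synthetic single-domain reference toxin
PFCAIDKDSCPRFWADCVEQKCGRMQECKYQWCDD
>SYNTOX02 synthetic single-domain reference toxin
KMCTHPPKVCSTEFFFCFPRLCYKYYSCFNEYCWP
>SYNTOX03 synthetic single-domain reference toxin
TACPTWPKDCLNGVIRCEMGECLQKYTCVLEDCYS
>SYNTOX04 synthetic single-domain reference toxin
IQCPFLFIECARPWNHCTYFECFVVVTCYIMACGK
>SYNTOX05 synthetic single-domain reference toxin
NFCLVRLAECKPIFNPCVHNHCYHEPECEMERCRL
>SYNTOX06 synthetic single-domain reference toxin
QSCPNQQDGCRAEHQPCNVTPCKKPLQCVDLICSW
>SYNTOX07 synthetic single-domain reference toxin
WNCFMSVLACPWSNWICEEIDCTNHEDCYNDACKE
>SYNTOX08 synthetic single-domain reference toxin
SACELWAIRCVDVAQKCKNHQCSEMHKCYSFSCKT
>SYNTOX09 synthetic single-domain reference toxin
RMCHAAAPECWHQDSSCIMWACRTMDMCLEYSCGQ
>SYNTOX10 synthetic single-domain reference toxin
GECGIPHGECLERWGLCPGGACMMQMKCHEMGCGG
>SYNTOX11 synthetic single-domain reference toxin
HMCKYDWVKCSMKNDPCQVGICRPWMDCMFDFCSG
>SYNTOX12 synthetic single-domain reference toxin
VWCRMPGLNCEQSQQHCWAMHCFLRIWCYLGLCDM
>SYNTOX13 synthetic single-domain reference toxin
YQCEGEVAECHHDGPSCHHRMCMMDENCAPKWCGD
>SYNTOX14 synthetic single-domain reference toxin
DQCSHNMGFCTGSFRWCAYLTCDLTAFCNSQTCWY
>SYNTOX15 synthetic single-domain reference toxin
EVCIDMGRSCDEHRAICSGIQCMQGYQCQPWGCVY
>SYNTOX16 synthetic single-domain reference toxin
DACDINSMHCRNGFPVCQPKYCAQNLYCFMQECMA
>SYNTOX17 synthetic single-domain reference toxin
WGCNTWVMQCSVNMVTCIHLDCQSDRVCERIICWF
>SYNTOX18 synthetic single-domain reference toxin
FYCMNFFERCHIYNNKCLGHSCYQESHCWFEICSK
>SYNTOX19 synthetic single-domain reference toxin
QSCPTWKEFCVLDGAICTRRQCMHEHLCDQSRCSL
>SYNTOX20 synthetic single-domain reference toxin
IDCGGGWEGCGVRWAFCDLQYCIKEYICTTIHCMK
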