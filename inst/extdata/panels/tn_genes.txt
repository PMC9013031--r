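CG001
CG002
CG003
CG004
CG005
CG006
CG007
CG008
CG009
CG010
CG011
CG012
CG013
CG014
CG015
CG016
CG017
CG018
CG019
CG020
CG021
CG022
CG023
CG024
CG025
CG026
CG027
CG028
CG029
CG030
CG031
CG032
CG033
CG034
CG035
CG036
CG037
CG038
CG039
CG040
CG041
CG042
CG043
CG044
CG045
CG046
CG047
CG048
CG049
CG050
CG051
CG052
CG053
CG054
CG055
CG056
CG057
CG058
CG059
CG060
CG061
CG062
CG063
CG064
CG065
CG066
CG067
CG068
CG069
CG070
CG071
CG072
CG073
CG074
CG075
CG076
CG077
CG078
CG079
CG080
CG081
CG082
CG083
CG084
CG085
CG086
CG087
CG088
CG089
CG090
CG091
CG092
TNG001
TNG002
TNG003
TNG004
TNG005
TNG006
TNG007
TNG008
TNG009
TNG010
TNG011
TNG012
TNG013
TNG014
TNG015
TNG016
TNG017
TNG018
TNG019
TNG020
TNG021
TNG022
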