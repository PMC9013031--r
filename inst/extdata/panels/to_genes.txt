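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
TOG001
TOG002
TOG003
TOG004
TOG005
TOG006
TOG007
TOG008
TOG009
TOG010
TOG011
TOG012
TOG013
TOG014
TOG015
TOG016
TOG017
TOG018
TOG019
TOG020
TOG021
TOG022
TOG023
TOG024
TOG025
TOG026
TOG027
TOG028
TOG029
TOG030
TOG031
TOG032
TOG033
TOG034
TOG035
TOG036
TOG037
TOG038
TOG039
TOG040
TOG041
TOG042
TOG043
TOG044
TOG045
TOG046
TOG047
TOG048
TOG049
TOG050
TOG051
TOG052
TOG053
TOG054
TOG055
TOG056
TOG057
TOG058
TOG059
TOG060
TOG061
TOG062
TOG063
TOG064
TOG065
TOG066
TOG067
TOG068
TOG069
TOG070
TOG071
TOG072
TOG073
TOG074
TOG075
TOG076
TOG077
TOG078
TOG079
TOG080
TOG081
TOG082
TOG083
TOG084
TOG085
TOG086
TOG087
TOG088
TOG089
TOG090
TOG091
TOG092
TOG093
TOG094
TOG095
TOG096
TOG097
TOG098
TOG099
TOG100
TOG101
TOG102
TOG103
TOG104
TOG105
TOG106
TOG107
TOG108
TOG109
TOG110
TOG111
TOG112
TOG113
TOG114
TOG115
TOG116
TOG117
TOG118
TOG119
TOG120
TOG121
TOG122
TOG123
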